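# Shared fixtures, built in code at test time.

tb_bodipy <- dye_pair_registry()$bodipy
tb_cy3 <- dye_pair_registry()$cy3

# noiseless default ground truth over the NBD reference table
noiseless_truth <- function(...) ground_truth(...)

# a decay trace synthesized directly from components (bypassing the truth
# table), for fitter unit tests
component_trace <- function(amplitudes, lifetimes, delay = 0.2, duration = 10,
                            dt = 0.01, channel = "cy3", noise_sd = 0,
                            seed = NULL) {
  t <- seq(delay, duration, by = dt)
  I <- drop(exp(-outer(t, 1 / lifetimes)) %*% amplitudes)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    I <- I + rnorm(length(I), 0, noise_sd * sqrt(pmax(I, 0)))
  }
  decay_trace(t, I, channel = channel, delay = delay)
}

# identity-pair toy conformer targets spanning the three states
toy_targets <- function() {
  list(closed = c("13" = 35.4, "51" = 37.7, "774" = 35.7),
       partially_open = c("13" = 51.0, "51" = 46.2, "774" = 48.65),
       open = c("13" = 77.8, "51" = 78.0, "774" = 83.5))
}

toy_q_grid <- function(n = 200L) seq(0.01, 0.35, length.out = n)
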