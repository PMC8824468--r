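test_that("profile constructor and 3-column text I/O behave", {
  q <- toy_q_grid(50)
  p <- saxs_profile(q, exp(-q), sigma = rep(0.01, 50), label = "x")
  f <- tempfile(fileext = ".dat")
  write_saxs_profile(p, f)
  back <- read_saxs_profile(f)
  expect_equal(back$q, p$q)
  expect_equal(back$intensity, p$intensity, tolerance = 1e-12)
  expect_equal(back$sigma, p$sigma)
  expect_error(saxs_profile(rev(q), exp(-q)), "increasing")
  expect_error(saxs_profile(q, exp(-q), sigma = rep(0, 50)), "positive")
})

test_that("Debye profile matches closed forms and the forward limit", {
  q <- toy_q_grid(80)
  # single unit bead scatters flat
  one <- debye_profile(bead_model(matrix(0, 1, 3)), q)
  expect_equal(one$intensity, rep(1, 80))
  # two beads at separation d: I(q) = 2 (1 + sin(qd)/(qd))
  d <- 25
  two <- debye_profile(bead_model(rbind(c(0, 0, 0), c(d, 0, 0))), q)
  expect_equal(two$intensity, 2 * (1 + sin(q * d) / (q * d)),
               tolerance = 1e-12)
  # forward-scattering limit (sum of form factors)^2
  set.seed(3)
  m <- bead_model(matrix(rnorm(30, sd = 10), 10, 3),
                  form_factors = runif(10, 0.5, 2))
  p <- debye_profile(m, c(1e-4, 0.01))
  expect_equal(p$intensity[1], sum(m$form_factors)^2, tolerance = 1e-3)
  expect_error(debye_profile(bead_model(matrix(0, 1, 3)), c(-0.1, 0.1)),
               "positive")
})

test_that("vectorized Debye sum equals the naive double loop", {
  set.seed(17)
  for (rep in 1:3) {
    n <- sample(5:20, 1)
    pos <- matrix(rnorm(3 * n, sd = 20), n, 3)
    ff <- runif(n, 0.5, 2)
    q <- toy_q_grid(40)
    fast <- debye_profile(bead_model(pos, ff), q)$intensity
    slow <- vapply(q, function(qq) {
      s <- 0
      for (i in 1:n) for (j in 1:n) {
        r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
        s <- s + ff[i] * ff[j] * (if (r == 0) 1 else sin(qq * r) / (qq * r))
      }
      s
    }, numeric(1))
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("scale-optimized chi-square has the closed-form optimum", {
  q <- toy_q_grid(60)
  th <- saxs_profile(q, 5 * exp(-10 * q^2) + 1)
  ex <- saxs_profile(q, 2 * th$intensity, sigma = rep(1, 60))
  res <- chi2_with_scale(ex, th)
  expect_equal(res$scale, 2, tolerance = 1e-12)
  expect_equal(res$chi2, 0, tolerance = 1e-20)
  # perturbed data: chi2 matches an independent direct summation
  set.seed(5)
  eps <- rnorm(60, 0, 0.05)
  ex2 <- saxs_profile(q, th$intensity + eps, sigma = runif(60, 0.02, 0.1))
  res2 <- chi2_with_scale(ex2, th)
  brute <- function(cc) mean(((ex2$intensity - cc * th$intensity) /
                                ex2$sigma)^2)
  expect_equal(res2$chi2, brute(res2$scale), tolerance = 1e-12)
  # the closed-form scale is the minimizer
  expect_lt(res2$chi2, min(brute(res2$scale * 1.001), brute(res2$scale * 0.999)))
  # conventions and error handling
  expect_equal(chi2_with_scale(ex2, th, normalization = "M-1")$chi2,
               res2$chi2 * 60 / 59, tolerance = 1e-12)
  th_off <- saxs_profile(q + 0.001, th$intensity)
  expect_error(chi2_with_scale(ex2, th_off), "interpolation")
  expect_silent(chi2_with_scale(ex2, th_off, interpolate = TRUE))
})

test_that("population fitting recovers noiseless mixture weights exactly", {
  conf <- build_toy_conformers(toy_targets())
  q <- toy_q_grid()
  profs <- lapply(conf, function(s) debye_profile(s$beads, q))
  mix <- simulate_saxs_mixture(profs[c("closed", "open")], c(0.81, 0.19))
  fit <- fit_populations(mix, profs[c("closed", "open")], n_states = 2)
  expect_equal(unname(fit$weights), c(0.81, 0.19), tolerance = 1e-9)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_lt(fit$chi2, 1e-12)
  # single-state fit reduces to chi2_with_scale
  one <- fit_populations(mix, profs["closed"], n_states = 1)
  expect_equal(one$chi2, chi2_with_scale(mix, profs$closed)$chi2,
               tolerance = 1e-9)
  expect_equal(unname(one$weights), 1)
  # identical profiles flagged non-identifiable
  expect_warning(dup <- fit_populations(mix, list(profs$closed, profs$closed),
                                        n_states = 2), "identical")
  expect_false(dup$identifiable)
})

test_that("NNLS population solution agrees with a dense simplex grid search", {
  conf <- build_toy_conformers(toy_targets()[c("closed", "open")])
  q <- toy_q_grid(100)
  profs <- lapply(conf, function(s) debye_profile(s$beads, q))
  mix <- simulate_saxs_mixture(profs, c(0.7, 0.3), noise = 0.01, seed = 8)
  fit <- fit_populations(mix, profs, n_states = 2)
  # independent oracle: scan w on a 0.5% grid, scale by closed form
  grid <- seq(0, 1, by = 0.005)
  chi2_at <- function(w) {
    ith <- w * profs$closed$intensity + (1 - w) * profs$open$intensity
    chi2_with_scale(mix, saxs_profile(q, ith))$chi2
  }
  best_w <- grid[which.min(vapply(grid, chi2_at, numeric(1)))]
  expect_equal(unname(fit$weights["closed"]), best_w, tolerance = 0.005)
  expect_lte(fit$chi2, chi2_at(best_w) + 1e-9)
})

test_that("adding a state never increases the minimized chi-square", {
  conf <- build_toy_conformers(toy_targets())
  q <- toy_q_grid(100)
  profs <- lapply(conf, function(s) debye_profile(s$beads, q))
  mix <- simulate_saxs_mixture(profs, c(0.5, 0.3, 0.2), noise = 0.02,
                               seed = 21)
  chi2s <- vapply(1:3, function(k)
    fit_populations(mix, profs, n_states = k)$chi2, numeric(1))
  expect_true(all(diff(chi2s) <= 1e-9))
})

test_that("single-state ranking orders models by goodness of fit", {
  conf <- build_toy_conformers(toy_targets())
  q <- toy_q_grid(100)
  profs <- lapply(conf, function(s) debye_profile(s$beads, q))
  # experiment equal to one profile: that one ranks first with chi2 ~ 0
  ex <- simulate_saxs_mixture(profs["partially_open"], 1)
  rk <- rank_single_states(ex, profs)
  expect_equal(rk$label[1], "partially_open")
  expect_lt(rk$chi2[1], 1e-12)
  # majority component of a mixture ranks first
  mix <- simulate_saxs_mixture(profs[c("closed", "open")], c(0.85, 0.15))
  rk2 <- rank_single_states(mix, profs[c("closed", "open")])
  expect_equal(rk2$label[1], "closed")
  expect_error(rank_single_states(ex, list()), "no theoretical")
})
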