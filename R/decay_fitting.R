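# Multi-exponential emission decay fitting: variable-projection multistart,
# AICc model selection, instrument-response stripping.

#' Time-resolved emission decay trace
#'
#' A sampled emission decay collected after the gating delay (detection is
#' delayed so that autofluorescence, direct acceptor excitation and scatter
#' have died away before the first sample).
#'
#' @param times sample times in ms, strictly increasing, starting at or after
#'   the delay.
#' @param intensities nonnegative intensities, same length as \code{times}.
#' @param channel one of \code{"donor"}, \code{"bodipy"}, \code{"cy3"}.
#' @param delay acquisition delay in ms (default 0.2).
#' @param metadata named list: sample id, condition, probe pair, replicate.
#' @return An object of class \code{"decay_trace"}.
#' @export
decay_trace <- function(times, intensities,
                        channel = c("donor", "bodipy", "cy3"),
                        delay = 0.2, metadata = list()) {
  channel <- match.arg(channel)
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  if (length(times) != length(intensities))
    stop("'times' and 'intensities' must have equal length", call. = FALSE)
  if (length(times) < 50L)
    stop("a decay trace needs at least 50 samples", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (times[1L] < delay - 1e-12)
    stop("first sample precedes the acquisition delay", call. = FALSE)
  structure(list(times = times, intensities = intensities, channel = channel,
                 delay = delay, metadata = metadata),
            class = "decay_trace")
}

#' @export
print.decay_trace <- function(x, ...) {
  cat(sprintf("Decay trace [%s]: %d points, t = %.3g..%.3g ms\n",
              x$channel, length(x$times), x$times[1L],
              x$times[length(x$times)]))
  invisible(x)
}

#' Read and write decay traces as 2-column delimited text
#'
#' The on-disk format is plain text: a header block of \code{# key: value}
#' lines (channel, delay and any metadata), then two whitespace-separated
#' columns \code{time_ms intensity}.
#'
#' @param path file path.
#' @return \code{read_decay_trace} returns a [decay_trace()];
#'   \code{write_decay_trace} returns \code{path} invisibly.
#' @export
read_decay_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    i <- regexpr(":", kv, fixed = TRUE)
    if (i > 0)
      meta[[trimws(substr(kv, 1L, i - 1L))]] <- trimws(substr(kv, i + 1L,
                                                              nchar(kv)))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  mat <- utils::read.table(text = body, col.names = c("time_ms", "intensity"))
  channel <- meta$channel %||% "donor"
  delay <- as.numeric(meta$delay %||% mat$time_ms[1L])
  meta$channel <- NULL; meta$delay <- NULL
  decay_trace(mat$time_ms, mat$intensity, channel = channel, delay = delay,
              metadata = meta)
}

#' @rdname read_decay_trace
#' @param trace a [decay_trace()].
#' @export
write_decay_trace <- function(trace, path) {
  stopifnot(inherits(trace, "decay_trace"))
  hdr <- c(sprintf("# channel: %s", trace$channel),
           sprintf("# delay: %.6g", trace$delay),
           vapply(names(trace$metadata),
                  function(k) sprintf("# %s: %s", k, trace$metadata[[k]]),
                  character(1)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(data.frame(trace$times, trace$intensities), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Amplitudes (and baseline) for fixed lifetimes by weighted linear least
# squares (variable projection).  The search path uses plain QR for speed;
# the final call uses Lawson-Hanson NNLS so reported amplitudes are
# nonnegative.
.vp_amplitudes <- function(times, intensities, taus, w, nonneg = FALSE) {
  X <- cbind(exp(-outer(times, 1 / taus)), 1)
  if (nonneg) {
    fit <- tryCatch(pracma::lsqnonneg(X * w, intensities * w),
                    error = function(e) NULL)
    cf <- if (is.null(fit))
      pmax(stats::coef(stats::lm.fit(X * w, intensities * w)), 0)
    else fit$x
  } else {
    cf <- stats::coef(stats::lm.fit(X * w, intensities * w))
    cf[is.na(cf)] <- 0
  }
  resid <- w * (intensities - X %*% cf)
  list(coef = as.numeric(cf), rss = sum(resid^2))
}

# Single n-component fit: variable-projection multistart over log-lifetimes,
# then joint bounded Levenberg-Marquardt refinement.  'w' are per-point
# weights (1/sigma); the returned rss is sigma-weighted.
.fit_n_exp <- function(times, intensities, n, w, n_starts = 8L) {
  t_min <- max(times[1L], 1e-3); t_max <- times[length(times)]
  lo <- log(t_min / 4); hi <- log(2 * t_max)
  # deterministic starts: n log-spaced quantile sets, staggered
  starts <- lapply(seq_len(n_starts), function(s) {
    off <- (s - 1) / n_starts * (hi - lo) / (n + 1)
    exp(seq(lo, hi, length.out = n + 2L)[2:(n + 1L)] + off -
          (hi - lo) / (2 * (n + 1)))
  })
  obj <- function(ltau) .vp_amplitudes(times, intensities, exp(ltau), w)$rss
  best <- NULL
  for (st in starts) {
    op <- stats::optim(log(st), obj, method = "Nelder-Mead",
                       control = list(maxit = 500L,
                                      reltol = 1e-12))
    if (is.null(best) || op$value < best$value) best <- op
  }
  taus <- sort(exp(best$par))
  amp <- .vp_amplitudes(times, intensities, taus, w, nonneg = TRUE)
  # joint refinement with all parameters free (bounded below at 0)
  a0 <- pmax(amp$coef[seq_len(n)], 1e-12 * max(intensities))
  b0 <- max(amp$coef[n + 1L], 0)
  resid_fn <- function(par) {
    a <- par[seq_len(n)]; tau <- par[n + seq_len(n)]; b <- par[2L * n + 1L]
    w * (intensities - drop(exp(-outer(times, 1 / tau)) %*% a) - b)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(a0, taus, b0), fn = resid_fn,
                       lower = rep(0, 2L * n + 1L),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500L, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    list(amplitudes = a0, lifetimes = taus, baseline = b0,
         rss = amp$rss, converged = FALSE)
  } else {
    p <- fit$par
    a <- p[seq_len(n)]; tau <- p[n + seq_len(n)]
    ord <- order(tau)
    rss <- sum(resid_fn(p)^2)
    # info 1-4: converged on ftol/ptol/gtol; 5: iteration cap with the best
    # point retained, still usable at these tolerances
    list(amplitudes = a[ord], lifetimes = tau[ord], baseline = p[2L * n + 1L],
         rss = rss, converged = is.finite(rss) && fit$info %in% 1:5)
  }
}

.aicc <- function(rss, n_obs, n_par) {
  k <- n_par + 1L  # + residual variance
  rss <- max(rss, .Machine$double.xmin)
  n_obs * log(rss / n_obs) + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Fit a multi-exponential model to a decay trace
#'
#' Fits \eqn{I(t) = \sum_i a_i e^{-t/\tau_i} + b} by nonlinear least squares
#' (variable projection over lifetimes with nonnegative amplitudes, followed
#' by joint Levenberg-Marquardt refinement).  With
#' \code{n_components = "auto"} both the 2- and 3-component models are fitted
#' and the component count is chosen by small-sample-corrected AIC, requiring
#' an AICc improvement of at least \code{delta_aicc} before accepting the
#' richer model.  Components faster than \code{strip_threshold} (default
#' 0.1 ms) reflect the instrument response, not energy transfer, and are
#' removed from the returned component list.
#'
#' @param trace a [decay_trace()].
#' @param n_components 2, 3 or \code{"auto"}.
#' @param strip_threshold lifetime (ms) below which a fitted component is
#'   treated as instrument response and discarded.
#' @param delta_aicc AICc margin the 3-component model must beat the
#'   2-component model by (default 2).
#' @param weighting \code{"poisson"} (default) weights residuals by
#'   \eqn{1/\sqrt{I}} as appropriate for shot-noise-limited photon detection;
#'   \code{"none"} fits unweighted.  Model selection uses the weighted
#'   residual sum of squares either way.
#' @param n_starts number of multistart lifetime seeds per model.
#' @return A \code{"lifetime_fit"}: \code{components} (data.frame with
#'   \code{amplitude}, \code{lifetime}, sorted by lifetime), \code{baseline},
#'   \code{residual_norm} (residual 2-norm relative to the signal 2-norm),
#'   \code{n_selected} (component count before stripping),
#'   \code{instrument_stripped} flag and the discarded \code{stripped}
#'   components.
#' @export
fit_decay <- function(trace, n_components = "auto", strip_threshold = 0.1,
                      delta_aicc = 2, weighting = c("poisson", "none"),
                      n_starts = 8L) {
  stopifnot(inherits(trace, "decay_trace"))
  weighting <- match.arg(weighting)
  y <- trace$intensities
  if (any(!is.finite(y)))
    stop("invalid trace: non-finite intensities", call. = FALSE)
  if (all(y == 0) || max(y) <= 0)
    stop("invalid trace: all intensities are zero", call. = FALSE)
  cand <- if (identical(n_components, "auto")) c(2L, 3L)
          else as.integer(n_components)
  if (!all(cand %in% 2:3))
    stop("'n_components' must be 2, 3 or \"auto\"", call. = FALSE)
  n_obs <- length(y)
  if (n_obs < 3L * (2L * max(cand) + 1L))
    stop("under-determined fit: ", n_obs, " points for ",
         2L * max(cand) + 1L, " parameters", call. = FALSE)
  w <- if (weighting == "poisson") 1 / sqrt(pmax(y, max(y) * 1e-4)) else
    rep(1, n_obs)
  fits <- lapply(cand, function(n) .fit_n_exp(trace$times, y, n, w, n_starts))
  if (length(fits) == 1L) {
    sel <- 1L
  } else {
    aicc <- mapply(function(f, n) .aicc(f$rss, n_obs, 2L * n + 1L), fits, cand)
    sel <- if (aicc[2L] < aicc[1L] - delta_aicc) 2L else 1L
  }
  f <- fits[[sel]]
  if (!f$converged)
    stop("decay fit did not converge (best residual sum of squares ",
         signif(f$rss, 4), ")", call. = FALSE)
  comp <- data.frame(amplitude = f$amplitudes, lifetime = f$lifetimes)
  # prune numerically-zero amplitudes (over-parameterized fits collapse)
  comp <- comp[comp$amplitude > 1e-8 * sum(comp$amplitude), , drop = FALSE]
  keep <- comp$lifetime >= strip_threshold
  structure(list(
    components = comp[keep, , drop = FALSE],
    stripped = comp[!keep, , drop = FALSE],
    baseline = f$baseline,
    residual_norm = sqrt(f$rss) / sqrt(sum((w * y)^2)),
    n_selected = cand[sel],
    instrument_stripped = TRUE,
    channel = trace$channel
  ), class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("Lifetime fit [%s]: %d-exponential, %d physical component(s)\n",
              x$channel, x$n_selected, nrow(x$components)))
  if (nrow(x$components))
    print(format(x$components, digits = 4), row.names = FALSE)
  cat(sprintf("relative residual norm %.3g\n", x$residual_norm))
  invisible(x)
}

#' Donor-only lifetime from a donor-channel decay
#'
#' Fits a two-exponential model and returns the longer lifetime together
#' with its fractional amplitude.  Donor-only decays are well described by
#' two exponentials with the long component carrying most of the signal; a
#' warning is raised when the long component carries less than
#' \code{min_fraction} (default 0.85) of the total amplitude, the quality
#' rule used to accept a donor lifetime for distance analysis.
#'
#' @param trace a donor-channel [decay_trace()].
#' @param min_fraction minimum acceptable amplitude fraction of the long
#'   component.
#' @return List with \code{tau_d} (ms), \code{amplitude_fraction} and the
#'   underlying \code{fit}.
#' @export
fit_donor_lifetime <- function(trace, min_fraction = 0.85) {
  stopifnot(inherits(trace, "decay_trace"))
  if (trace$channel != "donor")
    stop("'trace' is not a donor-channel trace", call. = FALSE)
  fit <- fit_decay(trace, n_components = 2L, strip_threshold = 0)
  comp <- fit$components
  i <- which.max(comp$lifetime)
  frac <- comp$amplitude[i] / sum(comp$amplitude)
  if (frac < min_fraction)
    warning(sprintf(paste0("long donor component carries only %.0f%% of the ",
                           "amplitude (< %.0f%%); lifetime may be unreliable"),
                    100 * frac, 100 * min_fraction), call. = FALSE)
  list(tau_d = comp$lifetime[i], amplitude_fraction = frac, fit = fit)
}

#' Distances encoded by the physical components of an acceptor-channel fit
#'
#' Converts each retained (post-stripping) component lifetime to a
#' donor-acceptor distance through Forster theory.  Components whose
#' lifetime is at or above the donor-only lifetime carry no energy transfer
#' and are rejected.
#'
#' @param fit a \code{"lifetime_fit"} from [fit_decay()].
#' @param tau_d donor-only lifetime (ms) at the probe position.
#' @param pair a [dye_pair()].
#' @param low_confidence_e efficiency below which a distance is flagged
#'   low-confidence.
#' @return Numeric vector of distances (A), sorted ascending, with a logical
#'   \code{"low_confidence"} attribute of the same length.
#' @export
channel_distances <- function(fit, tau_d, pair, low_confidence_e = 0.02) {
  stopifnot(inherits(fit, "lifetime_fit"), inherits(pair, "dye_pair"))
  if (!isTRUE(fit$instrument_stripped))
    stop("fit has not had the instrument component stripped", call. = FALSE)
  taus <- fit$components$lifetime
  taus <- taus[taus < tau_d]
  if (length(taus) == 0L)
    stop("no transferring components: every retained lifetime is at or ",
         "above the donor-only lifetime", call. = FALSE)
  e <- transfer_efficiency(taus, tau_d)
  d <- distance_from_efficiency(e, pair)
  ord <- order(d)
  structure(d[ord], low_confidence = (e < low_confidence_e)[ord])
}
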