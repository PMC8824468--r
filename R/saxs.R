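# Debye-formula scattering profiles from bead models, scale-optimized
# chi-square, and simplex-constrained multi-state population fitting.

#' Small-angle scattering profile
#'
#' @param q scattering vector magnitudes (1/A), strictly increasing, > 0.
#' @param intensity intensities (arbitrary units), finite.
#' @param sigma per-point uncertainties (> 0); required for fitting,
#'   may be NULL for theoretical profiles.
#' @param label optional profile label.
#' @return A \code{"saxs_profile"}.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL, label = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop("'q' and 'intensity' lengths differ", call. = FALSE)
  if (any(q <= 0) || any(diff(q) <= 0))
    stop("'q' must be positive and strictly increasing", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("non-finite intensities", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q) || any(sigma <= 0))
      stop("'sigma' must be positive and match 'q' in length", call. = FALSE)
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 label = label), class = "saxs_profile")
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("SAXS profile%s: %d points, q = %.3g..%.3g 1/A%s\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$q), x$q[1L], x$q[length(x$q)],
              if (is.null(x$sigma)) " (no sigma)" else ""))
  invisible(x)
}

#' Read/write 3-column scattering text files
#'
#' Beamline-pipeline convention: whitespace-separated columns
#' \code{q I sigma} (sigma optional), \code{#} comment lines ignored.
#'
#' @param path file path.
#' @return \code{read_saxs_profile} returns a \code{"saxs_profile"}.
#' @export
read_saxs_profile <- function(path) {
  df <- utils::read.table(path, comment.char = "#")
  saxs_profile(df[[1L]], df[[2L]],
               sigma = if (ncol(df) >= 3L) df[[3L]] else NULL,
               label = basename(path))
}

#' @rdname read_saxs_profile
#' @param profile a \code{"saxs_profile"}.
#' @export
write_saxs_profile <- function(profile, path) {
  stopifnot(inherits(profile, "saxs_profile"))
  df <- data.frame(q = profile$q, I = profile$intensity)
  if (!is.null(profile$sigma)) df$sigma <- profile$sigma
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# %s  (q  I%s)", profile$label %||% "saxs profile",
                     if (is.null(profile$sigma)) "" else "  sigma"), con)
  utils::write.table(df, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coarse bead model for scattering calculations
#'
#' @param positions n x 3 matrix of bead coordinates (A).
#' @param form_factors nonnegative per-bead weights (default 1).
#' @param label conformer name.
#' @return A \code{"bead_model"}.
#' @export
bead_model <- function(positions, form_factors = NULL, label = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L || ncol(positions) != 3L)
    stop("'positions' must be an n x 3 matrix with n >= 1", call. = FALSE)
  if (any(!is.finite(positions)))
    stop("non-finite bead coordinates", call. = FALSE)
  if (is.null(form_factors)) form_factors <- rep(1, nrow(positions))
  if (length(form_factors) != nrow(positions) || any(form_factors < 0))
    stop("'form_factors' must be nonnegative, one per bead", call. = FALSE)
  structure(list(positions = positions, form_factors = as.numeric(form_factors),
                 label = label), class = "bead_model")
}

#' @rdname bead_model
#' @param model a \code{"model_coordinates"} (one bead per restrained-atom
#'   position, unit form factors).
#' @export
bead_model_from_coordinates <- function(model, label = model$model_id) {
  stopifnot(inherits(model, "model_coordinates"))
  bead_model(as.matrix(model$coords[c("x", "y", "z")]), label = label)
}

#' Orientationally averaged scattering profile of a bead model (Debye sum)
#'
#' \deqn{I(q) = \sum_i \sum_j f_i f_j \frac{\sin(q r_{ij})}{q r_{ij}}}
#' with the \eqn{i = j} sinc limit equal to 1, so
#' \eqn{I(q \to 0) = (\sum_i f_i)^2}.  Uniform unit bead form factors by
#' default — no hydration layer or excluded-volume term, so absolute
#' goodness-of-fit values against detector data are not comparable to
#' atomistic form-factor calculators; relative state populations are.
#'
#' @param model a [bead_model()].
#' @param q_grid positive, increasing q values (1/A).
#' @return A theoretical \code{"saxs_profile"} (no sigma).
#' @export
debye_profile <- function(model, q_grid) {
  stopifnot(inherits(model, "bead_model"))
  q_grid <- as.numeric(q_grid)
  if (!length(q_grid) || any(q_grid <= 0) || any(diff(q_grid) <= 0))
    stop("'q_grid' must be positive and increasing", call. = FALSE)
  p <- model$positions; f <- model$form_factors
  rij <- as.matrix(stats::dist(p))
  ff <- outer(f, f)
  iy <- vapply(q_grid, function(q) {
    s <- q * rij
    sinc <- ifelse(s == 0, 1, sin(s) / s)
    sum(ff * sinc)
  }, numeric(1))
  saxs_profile(q_grid, iy, label = model$label)
}

.check_grids <- function(experimental, theoretical, interpolate) {
  if (isTRUE(all.equal(experimental$q, theoretical$q))) return(theoretical)
  if (!interpolate)
    stop("q grids differ and interpolation is disabled", call. = FALSE)
  saxs_profile(experimental$q,
               stats::approx(theoretical$q, theoretical$intensity,
                             xout = experimental$q, rule = 2)$y,
               label = theoretical$label)
}

#' Scale-optimized chi-square between an experimental and a model profile
#'
#' The global scale \eqn{c} minimizing
#' \eqn{\sum_m ((I_{exp}(q_m) - c I_{mod}(q_m))/\sigma_m)^2} has the closed
#' form \eqn{c = \sum I_{exp} I_{mod}/\sigma^2 / \sum I_{mod}^2/\sigma^2};
#' the reported \eqn{\chi^2} is the minimized sum divided by \eqn{M} (or
#' \eqn{M - 1} with \code{normalization = "M-1"}; conventions differ between
#' fitting programs).
#'
#' @param experimental \code{"saxs_profile"} with sigmas.
#' @param theoretical \code{"saxs_profile"} on the same q grid (or
#'   interpolated onto it when \code{interpolate = TRUE}).
#' @param interpolate linearly interpolate the theoretical profile onto the
#'   experimental grid (default FALSE).
#' @param normalization \code{"M"} (default) or \code{"M-1"}.
#' @return List with \code{scale} and \code{chi2}.
#' @export
chi2_with_scale <- function(experimental, theoretical, interpolate = FALSE,
                            normalization = c("M", "M-1")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(experimental, "saxs_profile"),
            inherits(theoretical, "saxs_profile"))
  if (is.null(experimental$sigma))
    stop("experimental profile has no sigma column", call. = FALSE)
  theoretical <- .check_grids(experimental, theoretical, interpolate)
  w <- 1 / experimental$sigma^2
  it <- theoretical$intensity; ie <- experimental$intensity
  cc <- sum(w * ie * it) / sum(w * it^2)
  m <- length(ie)
  denom <- if (normalization == "M") m else m - 1L
  list(scale = cc, chi2 = sum(w * (ie - cc * it)^2) / denom)
}

#' Fit state populations to an experimental scattering profile
#'
#' Finds nonnegative weights summing to one and a global scale minimizing
#' the sigma-weighted residual between the experiment and
#' \eqn{c \sum_k w_k I_k(q)}.  Because \eqn{c w_k} enters linearly, the
#' constrained problem reduces to nonnegative least squares on
#' sigma-whitened profiles followed by normalization (the scale is the
#' coefficient sum).  When \code{n_states} is smaller than the number of
#' supplied profiles, every subset of that size is fitted and the best kept
#' (mirroring multi-state ensemble fitting practice).  Numerically identical
#' profiles make the weights non-identifiable; this is detected and flagged.
#'
#' @param experimental \code{"saxs_profile"} with sigmas.
#' @param theoretical list of theoretical \code{"saxs_profile"}s.
#' @param n_states number of states to fit (default: all supplied).
#' @param interpolate interpolate theoretical profiles onto the experimental
#'   grid.
#' @param normalization chi-square normalization, see [chi2_with_scale()].
#' @return A \code{"population_fit"}: \code{weights} (named, on the
#'   simplex), \code{scale}, \code{chi2}, \code{n_states}, \code{states}
#'   (labels of the fitted subset) and \code{identifiable} flag.
#' @export
fit_populations <- function(experimental, theoretical,
                            n_states = length(theoretical),
                            interpolate = FALSE,
                            normalization = c("M", "M-1")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(experimental, "saxs_profile"))
  if (!length(theoretical)) stop("no theoretical profiles", call. = FALSE)
  if (inherits(theoretical, "saxs_profile")) theoretical <- list(theoretical)
  if (n_states < 1L || n_states > length(theoretical))
    stop("'n_states' must be between 1 and the number of profiles",
         call. = FALSE)
  if (is.null(experimental$sigma))
    stop("experimental profile has no sigma column", call. = FALSE)
  theoretical <- lapply(theoretical, .check_grids,
                        experimental = experimental, interpolate = interpolate)
  labels <- vapply(seq_along(theoretical), function(k)
    theoretical[[k]]$label %||% paste0("state", k), character(1))
  A_full <- vapply(theoretical, function(p) p$intensity,
                   numeric(length(experimental$q)))
  wt <- 1 / experimental$sigma
  b <- experimental$intensity * wt

  fit_subset <- function(idx) {
    A <- A_full[, idx, drop = FALSE] * wt
    nn <- pracma::lsqnonneg(A, b)
    coef <- nn$x
    rss <- sum((b - A %*% coef)^2)
    list(idx = idx, coef = coef, rss = rss)
  }
  subsets <- utils::combn(length(theoretical), n_states, simplify = FALSE)
  fits <- lapply(subsets, fit_subset)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]

  scale <- sum(best$coef)
  if (scale <= 0)
    stop("degenerate fit: all population coefficients are zero", call. = FALSE)
  weights <- stats::setNames(best$coef / scale, labels[best$idx])
  m <- length(b)
  chi2 <- best$rss / if (normalization == "M") m else m - 1L

  # non-identifiability: any two fitted profiles numerically identical
  identifiable <- TRUE
  if (n_states > 1L) {
    As <- A_full[, best$idx, drop = FALSE]
    for (i in seq_len(ncol(As) - 1L)) for (j in seq((i + 1L), ncol(As))) {
      if (isTRUE(all.equal(As[, i], As[, j], tolerance = 1e-10))) {
        identifiable <- FALSE
        warning("theoretical profiles '", labels[best$idx][i], "' and '",
                labels[best$idx][j], "' are numerically identical; ",
                "population split between them is arbitrary", call. = FALSE)
      }
    }
  }
  structure(list(weights = weights, scale = scale, chi2 = chi2,
                 n_states = n_states, states = labels[best$idx],
                 identifiable = identifiable),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("Population fit (%d state%s): chi2 = %.4g, scale = %.4g%s\n",
              x$n_states, if (x$n_states > 1L) "s" else "", x$chi2, x$scale,
              if (x$identifiable) "" else "  [non-identifiable]"))
  for (k in seq_along(x$weights))
    cat(sprintf("  %-20s %5.1f%%\n", names(x$weights)[k], 100 * x$weights[k]))
  invisible(x)
}

#' Rank candidate single-state models by scale-optimized chi-square
#'
#' @inheritParams fit_populations
#' @return data.frame with columns \code{label} and \code{chi2}, sorted
#'   ascending by chi2.
#' @export
rank_single_states <- function(experimental, theoretical,
                               interpolate = FALSE,
                               normalization = c("M", "M-1")) {
  normalization <- match.arg(normalization)
  if (!length(theoretical)) stop("no theoretical profiles", call. = FALSE)
  if (inherits(theoretical, "saxs_profile")) theoretical <- list(theoretical)
  chi2 <- vapply(theoretical, function(p)
    chi2_with_scale(experimental, p, interpolate = interpolate,
                    normalization = normalization)$chi2, numeric(1))
  labels <- vapply(seq_along(theoretical), function(k)
    theoretical[[k]]$label %||% paste0("state", k), character(1))
  out <- data.frame(label = labels, chi2 = chi2)
  out <- out[order(out$chi2), ]
  rownames(out) <- NULL
  out
}
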