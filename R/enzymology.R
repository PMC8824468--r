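# ATPase kinetics (Hill/Michaelis-Menten titration fitting) and single-site
# ligand saturation arithmetic.

#' ATPase titration series
#'
#' @param concentrations substrate concentrations in uM, nonnegative and
#'   increasing.
#' @param rates initial rates (pmol phosphate released per minute), same
#'   length.
#' @param sds optional per-point replicate SDs.
#' @return A \code{"titration_series"}.
#' @export
titration_series <- function(concentrations, rates, sds = NULL) {
  concentrations <- as.numeric(concentrations); rates <- as.numeric(rates)
  if (!length(concentrations))
    stop("empty concentration list", call. = FALSE)
  if (length(concentrations) != length(rates))
    stop("'concentrations' and 'rates' lengths differ", call. = FALSE)
  if (any(concentrations < 0) || any(diff(concentrations) <= 0))
    stop("'concentrations' must be nonnegative and increasing", call. = FALSE)
  if (any(!is.finite(rates))) stop("non-finite rates", call. = FALSE)
  structure(list(concentrations = concentrations, rates = rates, sds = sds),
            class = "titration_series")
}

#' @rdname titration_series
#' @param path delimited text with columns \code{concentration rate [sd]};
#'   \code{#} comments ignored.
#' @export
read_titration_series <- function(path) {
  df <- utils::read.table(path, comment.char = "#", header = FALSE)
  titration_series(df[[1L]], df[[2L]],
                   sds = if (ncol(df) >= 3L) df[[3L]] else NULL)
}

#' Fit the Hill-extended Michaelis-Menten equation to a titration
#'
#' Least-squares fit of
#' \deqn{v_0 = \frac{V_{max} [S]^n}{K_M^n + [S]^n}}
#' with \eqn{V_{max}} (pmol/min), \eqn{K_M} (uM) and the Hill coefficient
#' \eqn{n} free (or \eqn{n} fixed at 1 for the plain hyperbolic fit).
#' Initial guesses: \eqn{V_{max}} = maximum observed rate, \eqn{K_M} = the
#' concentration nearest half-maximal rate, \eqn{n = 1}.
#'
#' @param series a [titration_series()].
#' @param fix_n NULL (fit n) or a fixed value for n (e.g. 1).
#' @return A \code{"hill_fit"}: \code{vmax}, \code{km}, \code{n},
#'   \code{covariance} (of the free parameters), \code{residual_norm},
#'   \code{fitted} values and the input \code{series}.
#' @export
fit_hill_kinetics <- function(series, fix_n = NULL) {
  stopifnot(inherits(series, "titration_series"))
  conc <- series$concentrations; v <- series$rates
  if (length(unique(conc)) < 5L)
    stop("under-determined fit: at least 5 distinct concentrations needed",
         call. = FALSE)
  vmax0 <- max(v)
  km0 <- conc[which.min(abs(v - vmax0 / 2))]
  km0 <- max(km0, min(conc[conc > 0]))
  df <- data.frame(conc = conc, v = v)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200L, ftol = 1e-14,
                                     ptol = 1e-14)
  fit <- tryCatch({
    if (is.null(fix_n)) {
      minpack.lm::nlsLM(v ~ vmax * conc^n / (km^n + conc^n), data = df,
                        start = list(vmax = vmax0, km = km0, n = 1),
                        lower = c(1e-9, 1e-9, 1e-3), control = ctrl)
    } else {
      n_fixed <- fix_n
      minpack.lm::nlsLM(v ~ vmax * conc^n_fixed / (km^n_fixed + conc^n_fixed),
                        data = df, start = list(vmax = vmax0, km = km0),
                        lower = c(1e-9, 1e-9), control = ctrl)
    }
  }, error = function(e)
    stop("Hill fit did not converge: ", conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  structure(list(vmax = unname(cf["vmax"]), km = unname(cf["km"]),
                 n = if (is.null(fix_n)) unname(cf["n"]) else fix_n,
                 covariance = tryCatch(stats::vcov(fit),
                                       error = function(e) NULL),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fitted = stats::fitted(fit), series = series),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(paste0("Hill kinetics fit: Vmax = %.4g pmol/min, ",
                     "KM = %.4g uM, n = %.3g\n"), x$vmax, x$km, x$n))
  cat(sprintf("residual norm %.3g over %d points\n", x$residual_norm,
              length(x$series$rates)))
  invisible(x)
}

#' Predicted rate from a Hill fit
#'
#' @param object a \code{"hill_fit"}.
#' @param newdata concentrations (uM) at which to predict; defaults to the
#'   fitted series.
#' @param ... unused.
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$series$concentrations
          else as.numeric(newdata)
  object$vmax * conc^object$n / (object$km^object$n + conc^object$n)
}

#' Single-site ligand saturation
#'
#' Fraction of sites occupied at free ligand concentration L with
#' dissociation constant \eqn{K_D}: \eqn{L / (L + K_D)}.  Ligand depletion
#' is ignored (free = total), appropriate when the ligand is in large excess
#' over binding sites.
#'
#' @param ligand ligand concentration (uM), >= 0; vectorized.
#' @param kd dissociation constant (uM), > 0.
#' @return Fraction bound in \eqn{[0, 1)}.
#' @examples
#' fraction_bound(2000, 3)   # > 0.99 at 2 mM ligand, Kd 3 uM
#' @export
fraction_bound <- function(ligand, kd) {
  if (!is.numeric(kd) || length(kd) != 1L || kd <= 0)
    stop("'kd' must be a single positive number", call. = FALSE)
  if (any(ligand < 0)) stop("'ligand' must be >= 0", call. = FALSE)
  ligand / (ligand + kd)
}
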