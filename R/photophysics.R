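# Forster-theory core: lifetimes <-> transfer efficiency <-> distance.

#' Donor/acceptor dye pair
#'
#' A dye pair bundles a donor name, an acceptor name and the Forster radius
#' \eqn{R_0} (the separation at which transfer efficiency is 50\%).  The
#' built-in registry carries the two lanthanide pairs used throughout the
#' package: Tb3+ chelate with Bodipy FL (\eqn{R_0} = 44.9 A) and Tb3+ with
#' Cy3 (\eqn{R_0} = 61.2 A).
#'
#' @param donor donor name, e.g. \code{"Tb3+"}.
#' @param acceptor acceptor name, e.g. \code{"Bodipy FL"} or \code{"Cy3"}.
#' @param r0 Forster radius in Angstrom; must be positive.
#' @return An object of class \code{"dye_pair"}.
#' @examples
#' dye_pair("Tb3+", "Cy3", 61.2)
#' dye_pair_registry()
#' @export
dye_pair <- function(donor, acceptor, r0) {
  stopifnot(is.character(donor), is.character(acceptor))
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) || r0 <= 0)
    stop("'r0' must be a single positive number (Angstrom)", call. = FALSE)
  structure(list(donor = donor, acceptor = acceptor, r0 = as.numeric(r0)),
            class = "dye_pair")
}

#' @export
print.dye_pair <- function(x, ...) {
  cat(sprintf("Dye pair: %s -> %s, R0 = %.1f A\n", x$donor, x$acceptor, x$r0))
  invisible(x)
}

#' @rdname dye_pair
#' @param file optional path to a registry file overriding or extending the
#'   built-in pairs: either delimited text with columns
#'   \code{donor, acceptor, r0} or a YAML list of \code{{donor, acceptor, r0}}
#'   entries.
#' @export
dye_pair_registry <- function(file = NULL) {
  reg <- list(
    bodipy = dye_pair("Tb3+", "Bodipy FL", 44.9),
    cy3    = dye_pair("Tb3+", "Cy3", 61.2)
  )
  if (!is.null(file)) {
    if (!file.exists(file)) stop("registry file not found: ", file, call. = FALSE)
    ext <- tolower(tools::file_ext(file))
    entries <- if (ext %in% c("yml", "yaml")) {
      yaml::read_yaml(file)
    } else {
      df <- utils::read.table(file, header = TRUE, sep = "",
                              stringsAsFactors = FALSE)
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    }
    for (e in entries) {
      key <- tolower(gsub("[^A-Za-z0-9]+", "", e$acceptor))
      reg[[key]] <- dye_pair(e$donor, e$acceptor, as.numeric(e$r0))
    }
  }
  reg
}

#' Look up a registered dye pair by acceptor name
#'
#' @param acceptor acceptor name; matching is case-insensitive and ignores
#'   punctuation (\code{"bodipy"}, \code{"Bodipy FL"} and \code{"BodipyFL"}
#'   all resolve to the same pair).
#' @param registry a registry as returned by [dye_pair_registry()].
#' @return A \code{"dye_pair"}.
#' @export
get_dye_pair <- function(acceptor, registry = dye_pair_registry()) {
  key <- tolower(gsub("[^A-Za-z0-9]+", "", acceptor))
  hit <- which(vapply(names(registry), function(k) startsWith(key, k) ||
                        startsWith(k, key), logical(1)))
  if (length(hit) == 0L)
    stop("no registered dye pair with acceptor '", acceptor, "'", call. = FALSE)
  registry[[hit[1L]]]
}

#' Energy-transfer efficiency from donor-sensitized and donor-only lifetimes
#'
#' Computes \eqn{E = 1 - \tau_{DA}/\tau_D}, where \eqn{\tau_{DA}} is the
#' donor-sensitized acceptor lifetime and \eqn{\tau_D} the donor-only
#' lifetime.  Both are in milliseconds (lanthanide donors put them on the
#' ms scale).
#'
#' @param tau_da donor-sensitized acceptor lifetime (ms).
#' @param tau_d donor-only lifetime (ms).
#' @return Transfer efficiency in \eqn{[0, 1)}.  Vectorized over
#'   \code{tau_da}.
#' @examples
#' transfer_efficiency(1.0, 2.0)  # 0.5
#' @export
transfer_efficiency <- function(tau_da, tau_d) {
  if (!is.numeric(tau_da) || !is.numeric(tau_d) || anyNA(tau_da) || anyNA(tau_d))
    stop("lifetimes must be numeric and non-missing", call. = FALSE)
  if (any(tau_da <= 0) || any(tau_d <= 0))
    stop("lifetimes must be positive", call. = FALSE)
  if (any(tau_da > tau_d))
    stop("tau_da exceeds tau_d: a sensitized lifetime longer than the ",
         "donor-only lifetime is physically impossible (negative transfer)",
         call. = FALSE)
  1 - tau_da / tau_d
}

#' Distance from transfer efficiency
#'
#' Inverts the Forster relation \eqn{E = 1/(1 + (R/R_0)^6)} to
#' \eqn{R = R_0 (1/E - 1)^{1/6}}.  At \eqn{E = 0.5} the distance is exactly
#' \eqn{R_0}; the function is strictly decreasing in \eqn{E}.
#'
#' @param efficiency transfer efficiency, strictly inside \eqn{(0, 1)}.
#' @param pair a [dye_pair()].
#' @return Distance in Angstrom; vectorized over \code{efficiency}.
#' @examples
#' distance_from_efficiency(0.5, dye_pair("Tb3+", "Bodipy FL", 44.9))  # 44.9
#' @export
distance_from_efficiency <- function(efficiency, pair) {
  stopifnot(inherits(pair, "dye_pair"))
  if (!is.numeric(efficiency) || anyNA(efficiency))
    stop("'efficiency' must be numeric", call. = FALSE)
  if (any(efficiency <= 0) || any(efficiency >= 1))
    stop("efficiency must lie strictly in (0, 1): the distance is undefined ",
         "at the endpoints", call. = FALSE)
  pair$r0 * (1 / efficiency - 1)^(1 / 6)
}

#' Donor-sensitized lifetime expected at a given distance
#'
#' Exact algebraic inverse of the efficiency -> distance map: given a
#' donor-acceptor separation \eqn{R} and the donor-only lifetime
#' \eqn{\tau_D}, returns
#' \eqn{\tau_{DA} = \tau_D (1 - 1/(1 + (R/R_0)^6))}.  Used by the synthetic
#' decay generator; round-trips with [distance_from_lifetimes()] to machine
#' precision.
#'
#' @param distance separation in Angstrom (> 0).
#' @param pair a [dye_pair()].
#' @param tau_d donor-only lifetime (ms).
#' @return \eqn{\tau_{DA}} in ms; vectorized over \code{distance}.
#' @export
lifetime_from_distance <- function(distance, pair, tau_d) {
  stopifnot(inherits(pair, "dye_pair"))
  if (!is.numeric(distance) || any(!is.finite(distance)) || any(distance <= 0))
    stop("'distance' must be positive and finite", call. = FALSE)
  if (!is.numeric(tau_d) || length(tau_d) != 1L || tau_d <= 0)
    stop("'tau_d' must be a single positive lifetime (ms)", call. = FALSE)
  e <- 1 / (1 + (distance / pair$r0)^6)
  tau_d * (1 - e)
}

#' Single-replicate distance estimate from a pair of lifetimes
#'
#' Composes [transfer_efficiency()] and [distance_from_efficiency()].
#' Distances measured at very low efficiency sit on the flat tail of the
#' Forster curve and are flagged low-confidence; replicate aggregation
#' (sample mean and SD) happens downstream in [tabulate_conditions()].
#'
#' @inheritParams transfer_efficiency
#' @param pair a [dye_pair()].
#' @param low_confidence_e efficiency below which the distance is flagged
#'   low-confidence (default 0.02, roughly 1.9 Forster radii).
#' @return A \code{"distance_estimate"}: list with \code{mean} (A), \code{sd}
#'   (NA for a single replicate), \code{n_replicates = 1} and a
#'   \code{low_confidence} flag.
#' @examples
#' distance_from_lifetimes(1.0, 2.0, get_dye_pair("Cy3"))
#' @export
distance_from_lifetimes <- function(tau_da, tau_d, pair,
                                    low_confidence_e = 0.02) {
  e <- transfer_efficiency(tau_da, tau_d)
  if (any(e == 0))
    stop("zero transfer efficiency: tau_da equals tau_d, no distance defined",
         call. = FALSE)
  distance_estimate(distance_from_efficiency(e, pair), sd = NA_real_,
                    n_replicates = 1L, low_confidence = e < low_confidence_e)
}

#' @rdname distance_from_lifetimes
#' @param mean distance mean (A).
#' @param sd distance standard deviation across replicates (A), NA if a
#'   single replicate.
#' @param n_replicates number of replicates aggregated.
#' @param low_confidence flag for estimates from the flat low-efficiency tail.
#' @export
distance_estimate <- function(mean, sd = NA_real_, n_replicates = 1L,
                              low_confidence = FALSE) {
  stopifnot(is.numeric(mean), mean > 0, n_replicates >= 1L)
  if (!is.na(sd) && sd < 0) stop("sd must be >= 0", call. = FALSE)
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 n_replicates = as.integer(n_replicates),
                 low_confidence = isTRUE(any(low_confidence))),
            class = "distance_estimate")
}

#' @export
print.distance_estimate <- function(x, ...) {
  cat(sprintf("%.1f %s A (n = %d)%s\n", x$mean,
              if (is.na(x$sd)) "" else sprintf("+/- %.1f", x$sd),
              x$n_replicates,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}
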