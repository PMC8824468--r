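# Reconciling short-range (Bodipy) and long-range (Cy3) acceptor-channel
# distance lists into closed / partially open / open conformer distances.

#' Probe pair across the two protomers
#'
#' @param residue_a labeled residue number on protomer A.
#' @param residue_b labeled residue number on protomer B.
#' @return A \code{"probe_pair"}; \code{is_identity} is TRUE when the same
#'   residue is labeled on both protomers.
#' @export
probe_pair <- function(residue_a, residue_b = residue_a) {
  residue_a <- as.integer(residue_a); residue_b <- as.integer(residue_b)
  if (residue_a <= 0L || residue_b <= 0L)
    stop("residue numbers must be positive", call. = FALSE)
  structure(list(residue_a = residue_a, residue_b = residue_b,
                 is_identity = residue_a == residue_b),
            class = "probe_pair")
}

#' @export
format.probe_pair <- function(x, ...) {
  sprintf("%d-%d", x$residue_a, x$residue_b)
}

#' @export
print.probe_pair <- function(x, ...) {
  cat("Probe pair", format(x),
      if (x$is_identity) "(identity)\n" else "(mixed)\n")
  invisible(x)
}

.conditions <- c("apo", "ATP", "ATPgS", "ATP+hairpin", "ATP+ssDNA")

.as_estimate <- function(x) {
  if (is.null(x) || inherits(x, "distance_estimate")) x
  else distance_estimate(x)
}

#' Assign conformer states from per-channel distance lists
#'
#' The two acceptor channels see different distance windows: the short-radius
#' acceptor (Bodipy FL) resolves the closed and partially open separations
#' but is blind to the open state, while the long-radius acceptor (Cy3)
#' resolves the partially open and open separations but not the closed one.
#' When the longer Bodipy distance matches the shorter Cy3 distance the two
#' channels are reporting the same (partially open) conformer, and the full
#' three-state picture emerges.  Four canonical cases are routed:
#'
#' \describe{
#'   \item{case 1}{2 Bodipy + 2 Cy3 distances: closed = d1(Bodipy),
#'     partially open = (d2(Bodipy), d1(Cy3)) kept as separate channel
#'     values, open = d2(Cy3).  If the channel match exceeds the tolerance a
#'     warning is raised and the raw delta reported.}
#'   \item{case 2}{1 Bodipy + 2 Cy3, no channel match: closed = d(Bodipy),
#'     partially open = d1(Cy3), open = d2(Cy3).}
#'   \item{case 3}{1 Bodipy + 2 Cy3 with d(Bodipy) matching d1(Cy3): two
#'     states only, labeled \code{short} (matched) and \code{long}; naming
#'     them closed/partially open/open is left to the user via
#'     \code{state_map}.}
#'   \item{case 4}{single-channel input: generically labeled
#'     \code{short}/\code{long} states.}
#' }
#'
#' @param bodipy_distances sorted ascending numeric vector (A), 0-2 entries.
#' @param cy3_distances sorted ascending numeric vector (A), 0-2 entries.
#' @param pair a [probe_pair()].
#' @param condition condition label (\code{"apo"}, \code{"ATP"},
#'   \code{"ATPgS"}, \code{"ATP+hairpin"}, \code{"ATP+ssDNA"}).
#' @param match_tolerance maximum |d2(Bodipy) - d1(Cy3)| treated as a channel
#'   match; default \code{max(3, 2 * pooled_sd)}.
#' @param pooled_sd pooled replicate SD (A) used to widen the match
#'   tolerance, if known.
#' @param bodipy_max distance (A) beyond which a Bodipy-channel component is
#'   too weakly transferring to be trusted; such entries are flagged and
#'   dropped with a warning rather than assigned.
#' @param state_map optional named list mapping \code{"short"}/\code{"long"}
#'   to explicit state names for case 3/4 outputs.
#' @return A \code{"conformer_distances"} record: the per-state
#'   [distance_estimate()]s (\code{closed}, \code{partially_open_bodipy},
#'   \code{partially_open_cy3}, \code{open}, or \code{short}/\code{long}),
#'   \code{case_label} in 1-4 and \code{match_delta} (A) when both channels
#'   contribute a candidate match.
#' @export
assign_states <- function(bodipy_distances, cy3_distances, pair, condition,
                          match_tolerance = NULL, pooled_sd = 0,
                          bodipy_max = 80, state_map = NULL) {
  stopifnot(inherits(pair, "probe_pair"))
  condition <- match.arg(condition, .conditions)
  b <- sort(as.numeric(bodipy_distances)); cy <- sort(as.numeric(cy3_distances))
  if (length(b) > 2L || length(cy) > 2L)
    stop("more than two distances per channel: over-fitted decay ",
         "(at most two physical components are expected)", call. = FALSE)
  if (length(b) == 0L && length(cy) == 0L)
    stop("no signal: both channels are empty", call. = FALSE)
  if (any(b > bodipy_max)) {
    warning(sprintf(paste0("Bodipy-channel distance beyond %.0f A dropped ",
                           "(%s): transfer too weak for this acceptor to ",
                           "report reliably"), bodipy_max,
                    paste(sprintf("%.1f", b[b > bodipy_max]), collapse = ", ")),
            call. = FALSE)
    b <- b[b <= bodipy_max]
  }
  tol <- match_tolerance %||% max(3, 2 * pooled_sd)

  rec <- list(pair = pair, condition = condition, closed = NULL,
              partially_open_bodipy = NULL, partially_open_cy3 = NULL,
              open = NULL, short = NULL, long = NULL,
              case_label = NA_integer_, match_delta = NA_real_)
  lab <- function(generic) {
    if (!is.null(state_map) && !is.null(state_map[[generic]]))
      state_map[[generic]] else generic
  }

  if (length(b) == 2L && length(cy) == 2L) {
    rec$case_label <- 1L
    rec$match_delta <- abs(b[2L] - cy[1L])
    if (rec$match_delta > tol)
      warning(sprintf(paste0("channel match |d2(Bodipy) - d1(Cy3)| = %.1f A ",
                             "exceeds tolerance %.1f A for pair %s"),
                      rec$match_delta, tol, format(pair)), call. = FALSE)
    rec$closed <- .as_estimate(b[1L])
    rec$partially_open_bodipy <- .as_estimate(b[2L])
    rec$partially_open_cy3 <- .as_estimate(cy[1L])
    rec$open <- .as_estimate(cy[2L])
  } else if (length(b) == 1L && length(cy) == 2L) {
    rec$match_delta <- abs(b[1L] - cy[1L])
    if (rec$match_delta <= tol) {          # case 3: matched short state
      rec$case_label <- 3L
      rec[[lab("short")]] <- .as_estimate(mean(c(b[1L], cy[1L])))
      rec[[lab("long")]] <- .as_estimate(cy[2L])
    } else {                               # case 2: three states
      rec$case_label <- 2L
      rec$closed <- .as_estimate(b[1L])
      rec$partially_open_cy3 <- .as_estimate(cy[1L])
      rec$open <- .as_estimate(cy[2L])
    }
  } else if (length(b) == 0L) {            # case 4: Cy3 only
    rec$case_label <- 4L
    if (length(cy) == 1L) rec[[lab("short")]] <- .as_estimate(cy[1L])
    else {
      rec[[lab("short")]] <- .as_estimate(cy[1L])
      rec[[lab("long")]] <- .as_estimate(cy[2L])
    }
  } else if (length(cy) == 0L) {           # single-channel Bodipy input
    warning("Cy3 channel empty: states assigned from the Bodipy channel ",
            "alone and labeled generically", call. = FALSE)
    rec$case_label <- 4L
    rec[[lab("short")]] <- .as_estimate(b[1L])
    if (length(b) == 2L) rec[[lab("long")]] <- .as_estimate(b[2L])
  } else {                                 # 1 Bodipy + 1 Cy3 / 2 + 1
    rec$match_delta <- abs(b[length(b)] - cy[1L])
    if (rec$match_delta <= tol && length(b) == 2L) {
      rec$case_label <- 1L
      rec$closed <- .as_estimate(b[1L])
      rec$partially_open_bodipy <- .as_estimate(b[2L])
      rec$partially_open_cy3 <- .as_estimate(cy[1L])
    } else if (rec$match_delta <= tol) {
      rec$case_label <- 3L
      rec[[lab("short")]] <- .as_estimate(mean(c(b[1L], cy[1L])))
    } else {
      rec$case_label <- 2L
      rec$closed <- .as_estimate(b[1L])
      rec$partially_open_cy3 <- .as_estimate(cy[1L])
      if (length(b) == 2L) rec$partially_open_bodipy <- .as_estimate(b[2L])
    }
  }

  po_vals <- c(rec$partially_open_bodipy$mean, rec$partially_open_cy3$mean)
  means <- c(rec$closed$mean,
             if (length(po_vals)) mean(po_vals),
             rec$open$mean)
  if (length(means) > 1L && is.unsorted(means))
    warning("state ordering violated: closed < partially open < open does ",
            "not hold for pair ", format(pair), call. = FALSE)
  structure(rec, class = "conformer_distances")
}

#' @export
print.conformer_distances <- function(x, ...) {
  cat(sprintf("Conformer distances, pair %s, %s (case %d)\n",
              format(x$pair), x$condition, x$case_label))
  for (s in c("closed", "partially_open_bodipy", "partially_open_cy3",
              "open", "short", "long"))
    if (!is.null(x[[s]]))
      cat(sprintf("  %-22s %.1f A\n", s, x[[s]]$mean))
  if (!is.na(x$match_delta))
    cat(sprintf("  channel match delta    %.2f A\n", x$match_delta))
  invisible(x)
}

.state_cols <- c("closed", "partially_open_bodipy", "partially_open_cy3",
                 "open", "short", "long")

#' Aggregate per-replicate state assignments into a summary table
#'
#' Groups replicate \code{"conformer_distances"} records by probe pair and
#' condition and reports the sample mean and standard deviation per state.
#' Groups with fewer than \code{min_replicates} replicates are flagged; the
#' layout mirrors a conformer-distance report table with one row per
#' (pair, condition) and one column block per state.
#'
#' @param records list of \code{"conformer_distances"} records (replicates).
#' @param min_replicates replicate count below which a group is flagged
#'   (default 3).
#' @return A data.frame with columns \code{pair}, \code{condition},
#'   \code{state}, \code{mean}, \code{sd}, \code{n}, \code{flagged}.
#' @export
tabulate_conditions <- function(records, min_replicates = 3L) {
  if (length(records) == 0L) stop("no records to tabulate", call. = FALSE)
  stopifnot(all(vapply(records, inherits, logical(1), "conformer_distances")))
  rows <- do.call(rbind, lapply(records, function(r) {
    vals <- lapply(.state_cols, function(s) r[[s]])
    keep <- !vapply(vals, is.null, logical(1))
    if (!any(keep)) return(NULL)
    data.frame(pair = format(r$pair), condition = r$condition,
               state = .state_cols[keep],
               value = vapply(vals[keep], function(v) v$mean, numeric(1)))
  }))
  agg <- do.call(rbind, lapply(
    split(rows, list(rows$pair, rows$condition, rows$state), drop = TRUE),
    function(g) data.frame(
      pair = g$pair[1L], condition = g$condition[1L], state = g$state[1L],
      mean = mean(g$value),
      sd = if (nrow(g) > 1L) stats::sd(g$value) else NA_real_,
      n = nrow(g))))
  agg$flagged <- agg$n < min_replicates
  ord <- order(agg$pair, match(agg$condition, .conditions),
               match(agg$state, .state_cols))
  rownames(agg) <- NULL
  agg[ord, ]
}

#' Format a condition summary as a report mirroring the per-state layout
#'
#' @param summary a data.frame from [tabulate_conditions()].
#' @return Character vector of report lines (also printed when
#'   \code{quiet = FALSE}).
#' @param quiet suppress printing.
#' @export
format_state_report <- function(summary, quiet = FALSE) {
  fmt <- function(g, s) {
    i <- which(g$state == s)
    if (!length(i)) return("-")
    if (is.na(g$sd[i])) sprintf("%.1f", g$mean[i])
    else sprintf("%.1f +/- %.1f", g$mean[i], g$sd[i])
  }
  keys <- unique(summary[c("pair", "condition")])
  lines <- c(sprintf("%-10s %-12s %-14s %-26s %-14s", "pair", "condition",
                     "closed", "partially open (Bo, Cy3)", "open"))
  for (i in seq_len(nrow(keys))) {
    g <- summary[summary$pair == keys$pair[i] &
                 summary$condition == keys$condition[i], ]
    po <- paste(fmt(g, "partially_open_bodipy"),
                fmt(g, "partially_open_cy3"), sep = ", ")
    lines <- c(lines, sprintf("%-10s %-12s %-14s %-26s %-14s",
                              keys$pair[i], keys$condition[i],
                              fmt(g, "closed"), po, fmt(g, "open")))
  }
  if (!quiet) cat(lines, sep = "\n")
  invisible(lines)
}
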