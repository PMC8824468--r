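# State-resolved distances -> symmetric C-beta docking restraints
# (CNS/HADDOCK 'assign' dialect), dropout subsets, model validation.

.bounds_for <- function(target, cutoff = 75, narrow = 5, wide = 7) {
  # the wide bounds apply strictly above the cutoff: lifetimes giving very
  # long distances sit on the flat, error-prone tail of the transfer curve
  b <- ifelse(target > cutoff, wide, narrow)
  cbind(minus = b, plus = b)
}

.state_target <- function(rec, state, partially_open = "mean") {
  if (state == "partially_open") {
    vals <- c(rec$partially_open_bodipy$mean, rec$partially_open_cy3$mean)
    if (!length(vals)) return(NULL)
    if (partially_open == "both") return(vals)
    return(mean(vals))
  }
  rec[[state]]$mean
}

#' Build a symmetric docking restraint set from conformer distances
#'
#' Each probe pair contributes its state-resolved distance as an unambiguous
#' C-beta to C-beta restraint between the labeled residues on the two
#' protomer chains.  Mixed pairs (different residues on the two protomers)
#' are duplicated symmetrically — both (residue i on chain A, residue j on
#' chain B) and (j on A, i on B) — because the labeling cannot distinguish
#' the two protomers; identity pairs are already symmetric and yield one
#' restraint.  Bounds follow the distance-dependent rule: +/-
#' \code{narrow} A (default 5) up to \code{bounds_cutoff} (default 75 A,
#' inclusive) and +/- \code{wide} A (default 7) above it.
#'
#' @param conformers list of \code{"conformer_distances"} records.
#' @param state which state's distance to restrain: \code{"closed"},
#'   \code{"partially_open"}, \code{"open"}, \code{"short"} or \code{"long"}.
#' @param chain_map length-2 character vector naming the protomer chains
#'   (default \code{c("A", "B")}).
#' @param partially_open \code{"mean"} (one restraint at the mean of the two
#'   channel values) or \code{"both"} (one restraint per channel value).
#' @param bounds_cutoff,narrow,wide bounds rule parameters (A).
#' @param atom restrained atom name (default \code{"CB"}).
#' @param strict error (rather than skip with a warning) when a record lacks
#'   the requested state.
#' @return A \code{"restraint_set"}: data.frame with columns
#'   \code{segment_a}, \code{residue_a}, \code{segment_b}, \code{residue_b},
#'   \code{atom}, \code{target}, \code{minus}, \code{plus}, \code{state},
#'   \code{source_a}, \code{source_b}; attributes \code{state} and
#'   \code{provenance}.
#' @export
build_restraints <- function(conformers, state, chain_map = c("A", "B"),
                             partially_open = c("mean", "both"),
                             bounds_cutoff = 75, narrow = 5, wide = 7,
                             atom = "CB", strict = FALSE) {
  partially_open <- match.arg(partially_open)
  if (inherits(conformers, "conformer_distances")) conformers <- list(conformers)
  stopifnot(length(chain_map) == 2L)
  rows <- list()
  for (rec in conformers) {
    stopifnot(inherits(rec, "conformer_distances"))
    targets <- .state_target(rec, state, partially_open)
    if (is.null(targets)) {
      msg <- sprintf("state '%s' absent for pair %s", state, format(rec$pair))
      if (strict) stop(msg, call. = FALSE)
      warning(msg, ", skipped", call. = FALSE)
      next
    }
    ra <- rec$pair$residue_a; rb <- rec$pair$residue_b
    for (tg in targets) {
      rows[[length(rows) + 1L]] <-
        data.frame(segment_a = chain_map[1L], residue_a = ra,
                   segment_b = chain_map[2L], residue_b = rb,
                   atom = atom, target = tg, source_a = ra, source_b = rb)
      if (!rec$pair$is_identity)
        rows[[length(rows) + 1L]] <-
          data.frame(segment_a = chain_map[1L], residue_a = rb,
                     segment_b = chain_map[2L], residue_b = ra,
                     atom = atom, target = tg, source_a = ra, source_b = rb)
    }
  }
  if (!length(rows))
    stop("no restraints could be built: requested state absent everywhere",
         call. = FALSE)
  df <- do.call(rbind, rows)
  df <- cbind(df, .bounds_for(df$target, bounds_cutoff, narrow, wide))
  df$state <- state
  df <- df[order(df$segment_a, df$residue_a, df$segment_b, df$residue_b,
                 df$target), ]
  rownames(df) <- NULL
  structure(df, class = c("restraint_set", "data.frame"), state = state,
            provenance = list(built = format(Sys.time()),
                              partially_open = partially_open))
}

#' Export a restraint set as CNS/HADDOCK 'assign' statements
#'
#' One \code{assign} statement per restraint, in the dialect docking engines
#' consume for unambiguous distance restraints:
#' \preformatted{assign (segid A and resid 51 and name CB)
#'        (segid B and resid 13 and name CB) 45.40 5.00 5.00}
#' Ordering is stable (chain, residue, target), so exports are bit-exact
#' across runs.  An optional file of pass-through lines (e.g. ambiguous
#' interface restraints prepared elsewhere) is appended verbatim.
#'
#' @param set a \code{"restraint_set"}.
#' @param dialect only \code{"cns"} is implemented.
#' @param path optional output file; when NULL the lines are returned only.
#' @param append_file optional file whose lines are appended verbatim.
#' @return Character vector of output lines, invisibly when written to file.
#' @export
export_restraint_table <- function(set, dialect = "cns", path = NULL,
                                   append_file = NULL) {
  stopifnot(inherits(set, "restraint_set"))
  if (!identical(dialect, "cns"))
    stop("unknown restraint dialect: ", dialect, call. = FALSE)
  if (nrow(set) == 0L) stop("empty restraint set", call. = FALSE)
  if (any(is.na(set$segment_a)) || any(is.na(set$segment_b)))
    stop("restraint with missing chain id", call. = FALSE)
  lines <- sprintf(paste0("assign (segid %s and resid %d and name %s) ",
                          "(segid %s and resid %d and name %s) ",
                          "%.2f %.2f %.2f ! state=%s source=%d-%d"),
                   set$segment_a, set$residue_a, set$atom,
                   set$segment_b, set$residue_b, set$atom,
                   set$target, set$minus, set$plus,
                   set$state, set$source_a, set$source_b)
  if (!is.null(append_file)) lines <- c(lines, readLines(append_file))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @rdname export_restraint_table
#' @param text character vector of 'assign' lines (alternative to
#'   \code{path}).
#' @export
read_restraint_table <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- grep("^\\s*assign", lines, value = TRUE)
  if (!length(lines)) stop("no assign statements found", call. = FALSE)
  pat <- paste0("assign \\(segid (\\S+) and resid (\\d+) and name (\\S+)\\) ",
                "\\(segid (\\S+) and resid (\\d+) and name (\\S+)\\) ",
                "([0-9.]+) ([0-9.]+) ([0-9.]+)",
                "(?: ! state=(\\S+) source=(\\d+)-(\\d+))?")
  m <- regmatches(lines, regexec(pat, lines))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) stop("unparseable assign line: ", lines[which(bad)[1L]],
                     call. = FALSE)
  df <- do.call(rbind, lapply(m, function(g)
    data.frame(segment_a = g[2L], residue_a = as.integer(g[3L]),
               segment_b = g[5L], residue_b = as.integer(g[6L]),
               atom = g[4L], target = as.numeric(g[8L]),
               source_a = if (nzchar(g[12L])) as.integer(g[12L]) else NA,
               source_b = if (nzchar(g[13L])) as.integer(g[13L]) else NA,
               minus = as.numeric(g[9L]), plus = as.numeric(g[10L]),
               state = if (nzchar(g[11L])) g[11L] else NA_character_)))
  df <- df[, c("segment_a", "residue_a", "segment_b", "residue_b", "atom",
               "target", "source_a", "source_b", "minus", "plus", "state")]
  structure(df, class = c("restraint_set", "data.frame"),
            state = df$state[1L], provenance = list(read_from = path))
}

#' Remove every restraint derived from one probe position
#'
#' Reproduces the systematic dropout control used to check that no single
#' labeled position dominates a docking run: all restraints whose source
#' probe pair involves \code{probe_residue} on either protomer are removed.
#'
#' @param set a \code{"restraint_set"}.
#' @param probe_residue residue number of the probe position to drop.
#' @return The reduced \code{"restraint_set"} (a warning is raised if the
#'   residue appears in no restraint).
#' @export
dropout_subsets <- function(set, probe_residue) {
  stopifnot(inherits(set, "restraint_set"))
  probe_residue <- as.integer(probe_residue)
  hit <- set$source_a == probe_residue | set$source_b == probe_residue
  if (!any(hit))
    warning("probe residue ", probe_residue,
            " appears in no restraint; set unchanged", call. = FALSE)
  out <- set[!hit, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(set), state = attr(set, "state"),
            provenance = c(attr(set, "provenance"),
                           list(dropped = probe_residue)))
}

#' Restrained-atom coordinates of a structural model
#'
#' Holds one C-beta (C-alpha for glycine) position per (chain, residue).
#' \code{read_model_coordinates} extracts them from a PDB file (first model
#' of multi-model files unless \code{model} is given).
#'
#' @param coords data.frame with columns \code{chain}, \code{residue},
#'   \code{x}, \code{y}, \code{z}.
#' @param model_id identifier for reports.
#' @param cluster_id optional cluster label.
#' @return A \code{"model_coordinates"} object.
#' @export
model_coordinates <- function(coords, model_id = "model", cluster_id = NA) {
  stopifnot(is.data.frame(coords),
            all(c("chain", "residue", "x", "y", "z") %in% names(coords)))
  if (any(!is.finite(as.matrix(coords[c("x", "y", "z")]))))
    stop("non-finite coordinates", call. = FALSE)
  structure(list(coords = coords, model_id = model_id,
                 cluster_id = cluster_id),
            class = "model_coordinates")
}

#' @rdname model_coordinates
#' @param path PDB file path.
#' @export
read_model_coordinates <- function(path, model_id = basename(path),
                                   cluster_id = NA) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  cb <- at[at$elety == "CB", ]
  ca <- at[at$elety == "CA", ]
  # C-alpha fallback where no C-beta exists (glycine)
  key <- function(d) paste(d$chain, d$resno)
  missing_cb <- !(key(ca) %in% key(cb))
  if (any(missing_cb)) {
    warning(sum(missing_cb), " residue(s) lack a CB atom; using CA",
            call. = FALSE)
    cb <- rbind(cb, ca[missing_cb, ])
  }
  model_coordinates(data.frame(chain = cb$chain, residue = cb$resno,
                               x = cb$x, y = cb$y, z = cb$z),
                    model_id = model_id, cluster_id = cluster_id)
}

#' Write a model's restrained-atom coordinates as a PDB file
#'
#' Emits one CB pseudo-atom per (chain, residue); used by the synthetic
#' conformer builder so the PDB-reading validation path is exercised.
#'
#' @param model a \code{"model_coordinates"}.
#' @param path output PDB path.
#' @export
write_model_pdb <- function(model, path) {
  stopifnot(inherits(model, "model_coordinates"))
  co <- model$coords
  n <- nrow(co)
  xyz <- as.numeric(t(as.matrix(co[c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = co$residue,
                   chain = co$chain, resid = rep("ALA", n),
                   elety = rep("CB", n))
  invisible(path)
}

.lookup_xyz <- function(model, chain, residue) {
  co <- model$coords
  i <- which(co$chain == chain & co$residue == residue)
  if (!length(i))
    stop("model '", model$model_id, "' lacks coordinates for chain ", chain,
         " residue ", residue, call. = FALSE)
  as.numeric(co[i[1L], c("x", "y", "z")])
}

.model_pair_distance <- function(model, r) {
  sqrt(sum((.lookup_xyz(model, r$segment_a, r$residue_a) -
              .lookup_xyz(model, r$segment_b, r$residue_b))^2))
}

#' Validate a structural model against a restraint set
#'
#' Computes the Euclidean distance between the restrained atoms for every
#' restraint and compares it to the target.  A restraint is satisfied when
#' |model distance - target| <= \code{threshold}.
#'
#' @param model a \code{"model_coordinates"}.
#' @param set a \code{"restraint_set"}.
#' @param threshold satisfaction threshold in A (default 5); may be a vector
#'   recycled along the restraints for per-restraint or per-state thresholds.
#' @return A \code{"deviation_report"}: per-restraint data.frame
#'   (\code{model_distance}, \code{deviation}, \code{satisfied}) plus a
#'   \code{summary} attribute with \code{n_satisfied}, \code{n_total} and
#'   \code{max_abs_deviation}.
#' @export
validate_model <- function(model, set, threshold = 5) {
  stopifnot(inherits(model, "model_coordinates"), inherits(set, "restraint_set"))
  d <- vapply(seq_len(nrow(set)), function(i)
    .model_pair_distance(model, set[i, ]), numeric(1))
  dev <- d - set$target
  thr <- rep_len(threshold, nrow(set))
  rep_df <- data.frame(set[c("segment_a", "residue_a", "segment_b",
                             "residue_b", "target")],
                       model_distance = d, deviation = dev,
                       threshold = thr, satisfied = abs(dev) <= thr)
  structure(rep_df, class = c("deviation_report", "data.frame"),
            summary = list(n_satisfied = sum(rep_df$satisfied),
                           n_total = nrow(rep_df),
                           max_abs_deviation = max(abs(dev)),
                           model_id = model$model_id))
}

#' @export
print.deviation_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Model %s: %d / %d restraints satisfied, max |dev| = %.2f A\n",
              s$model_id, s$n_satisfied, s$n_total, s$max_abs_deviation))
  print.data.frame(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}

#' Write a deviation report as delimited text
#'
#' @param report a \code{"deviation_report"}.
#' @param path output TSV path.
#' @export
write_deviation_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Probe-pair distance consistency across docking clusters
#'
#' For each probe pair, computes the standard deviation of the model
#' (restrained-atom) distance across cluster-representative models — a
#' measure of how consistently independent clusters place the probes.
#'
#' @param models list of \code{"model_coordinates"}, one per cluster.
#' @param set a \code{"restraint_set"} defining the pairs to measure.
#' @return List with \code{per_pair} (data.frame of per-restraint SDs across
#'   clusters) and \code{average_sd}.
#' @export
cluster_consistency <- function(models, set) {
  stopifnot(inherits(set, "restraint_set"))
  if (length(models) < 2L)
    stop("cluster consistency needs at least two clusters", call. = FALSE)
  dists <- vapply(models, function(m)
    vapply(seq_len(nrow(set)), function(i)
      .model_pair_distance(m, set[i, ]), numeric(1)),
    numeric(nrow(set)))
  sds <- apply(matrix(dists, nrow = nrow(set)), 1L, stats::sd)
  per_pair <- data.frame(set[c("segment_a", "residue_a", "segment_b",
                               "residue_b")], sd = sds)
  list(per_pair = per_pair, average_sd = mean(sds))
}
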