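# Orchestration: configuration handling and staged runs from raw traces to
# state tables, restraint files, model validation and scattering fits.

#' Run configuration
#'
#' Loads (or builds) the configuration driving [run_pipeline()].  A config
#' round-trips losslessly through its YAML file representation.
#'
#' @param file YAML file path, or NULL to build from \code{...}.
#' @param ... configuration entries overriding the defaults (see Details).
#' @details Recognised entries: \code{seed}; \code{outdir};
#'   \code{simulate} (list: \code{construct}, \code{replicates},
#'   \code{noise_level}, \code{tau_d}); \code{manifest} (path to an existing
#'   trace manifest, skips simulation); \code{registry_file} (dye-pair
#'   overrides); \code{tolerances} (list: \code{match}, \code{validation});
#'   \code{bounds} (list: \code{cutoff}, \code{narrow}, \code{wide});
#'   \code{restraints} (list: \code{condition}, \code{states},
#'   \code{chain_map}, \code{dropouts}); \code{models} (named list: state ->
#'   PDB path); \code{saxs} (list: \code{experimental}, \code{theoretical},
#'   \code{n_states}); \code{kinetics} (titration file path).
#' @return A \code{"run_config"} list.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list(
    seed = 1L, outdir = "lretstates-run",
    simulate = list(construct = "NBD", replicates = 3L, noise_level = 0,
                    tau_d = 2.0),
    manifest = NULL, registry_file = NULL,
    tolerances = list(match = 3, validation = 5),
    bounds = list(cutoff = 75, narrow = 5, wide = 7),
    restraints = list(condition = "ATP",
                      states = c("closed", "partially_open", "open"),
                      chain_map = c("A", "B"), dropouts = FALSE),
    models = NULL, saxs = NULL, kinetics = NULL)
  over <- if (!is.null(file)) yaml::read_yaml(file) else list()
  over <- utils::modifyList(over, list(...))
  cfg <- utils::modifyList(cfg, over)
  if (any(unlist(cfg$tolerances) <= 0))
    stop("all tolerances must be positive", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a \code{"run_config"}.
#' @param path output YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulate, fit and assign states for one probe pair and condition
#'
#' Convenience wrapper chaining the full single-sample analysis:
#' [simulate_decay()] for both acceptor channels (when \code{truth} is
#' given) or user-supplied traces, [fit_decay()], [channel_distances()] and
#' [assign_states()].
#'
#' @param truth a [ground_truth()].
#' @param pair a [probe_pair()].
#' @param condition condition label.
#' @param replicate replicate index passed to the simulator.
#' @param n_components component-count policy for [fit_decay()].
#' @param ... passed to [assign_states()].
#' @return A \code{"conformer_distances"} record.
#' @export
recover_conformers <- function(truth, pair, condition, replicate = 1L,
                               n_components = "auto", ...) {
  reg <- dye_pair_registry()
  tau_d <- .truth_tau_d(truth, pair$residue_b)
  dists <- lapply(c(bodipy = "bodipy", cy3 = "cy3"), function(ch) {
    tr <- tryCatch(simulate_decay(truth, pair, condition, ch, replicate),
                   error = function(e) NULL)
    if (is.null(tr)) return(numeric(0))
    fit <- fit_decay(tr, n_components = n_components)
    channel_distances(fit, tau_d, reg[[ch]])
  })
  assign_states(dists$bodipy, dists$cy3, pair, condition, ...)
}

.stage_fit_decays <- function(manifest, dir, registry, n_components = "auto") {
  don <- manifest[manifest$channel == "donor", ]
  tau_d <- c()
  for (pos in unique(don$residue_a)) {
    fits <- vapply(don$file[don$residue_a == pos], function(f)
      fit_donor_lifetime(read_decay_trace(file.path(dir, f)))$tau_d,
      numeric(1))
    tau_d[as.character(pos)] <- mean(fits)
  }
  acc <- manifest[manifest$channel != "donor", ]
  rows <- list()
  for (i in seq_len(nrow(acc))) {
    tr <- read_decay_trace(file.path(dir, acc$file[i]))
    fit <- fit_decay(tr, n_components = n_components)
    td <- tau_d[as.character(acc$residue_b[i])]
    d <- tryCatch(channel_distances(fit, td, registry[[acc$channel[i]]]),
                  error = function(e) numeric(0))
    if (length(d))
      rows[[length(rows) + 1L]] <-
        data.frame(residue_a = acc$residue_a[i], residue_b = acc$residue_b[i],
                   condition = acc$condition[i], channel = acc$channel[i],
                   replicate = acc$replicate[i], distance = d)
  }
  list(distances = do.call(rbind, rows), tau_d = tau_d)
}

.stage_assign <- function(distances, match_tolerance) {
  keys <- unique(distances[c("residue_a", "residue_b", "condition",
                             "replicate")])
  records <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sel <- distances$residue_a == k$residue_a &
      distances$residue_b == k$residue_b &
      distances$condition == k$condition & distances$replicate == k$replicate
    g <- distances[sel, ]
    records[[i]] <- assign_states(
      g$distance[g$channel == "bodipy"], g$distance[g$channel == "cy3"],
      probe_pair(k$residue_a, k$residue_b), k$condition,
      match_tolerance = match_tolerance)
  }
  records
}

# conformer_distances records rebuilt from a tabulate_conditions() summary,
# one per (pair, condition), carrying group means
.records_from_summary <- function(summary) {
  keys <- unique(summary[c("pair", "condition")])
  lapply(seq_len(nrow(keys)), function(i) {
    g <- summary[summary$pair == keys$pair[i] &
                   summary$condition == keys$condition[i], ]
    res <- as.integer(strsplit(keys$pair[i], "-")[[1L]])
    rec <- list(pair = probe_pair(res[1L], res[2L]),
                condition = keys$condition[i], closed = NULL,
                partially_open_bodipy = NULL, partially_open_cy3 = NULL,
                open = NULL, short = NULL, long = NULL,
                case_label = NA_integer_, match_delta = NA_real_)
    for (j in seq_len(nrow(g)))
      rec[[g$state[j]]] <- distance_estimate(g$mean[j],
                                             sd = g$sd[j], n_replicates = g$n[j])
    structure(rec, class = "conformer_distances")
  })
}

#' Run the staged analysis pipeline
#'
#' Executes the selected stages in order: \code{simulate} (synthetic study
#' generation), \code{fit_decays}, \code{assign_states},
#' \code{build_restraints}, \code{validate_models}, \code{saxs_fit},
#' \code{kinetics_fit}.  Each stage writes its outputs under
#' \code{config$outdir} and the run finishes with a machine-readable
#' \code{run_log.yaml} recording the seed, versions and stages executed.
#' Stage outputs are pure functions of (inputs, config, seed): rerunning
#' with the same configuration reproduces them.
#'
#' @param config a [run_config()].
#' @param stages character vector of stages to run (default: all that the
#'   config provides inputs for).
#' @return A list of per-stage results (invisibly).
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "fit_decays", "assign_states",
                                    "build_restraints", "validate_models",
                                    "saxs_fit", "kinetics_fit")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- list()
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  registry <- dye_pair_registry(config$registry_file)
  trace_dir <- file.path(config$outdir, "traces")
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% stages) run_stage("simulate", {
    sim <- config$simulate
    dist_tab <- reference_distance_table(sim$construct %||% "NBD")
    if (!is.null(sim$conditions))
      dist_tab <- dist_tab[dist_tab$condition %in% sim$conditions, ]
    if (!is.null(sim$pairs))
      dist_tab <- dist_tab[paste(dist_tab$residue_a, dist_tab$residue_b,
                                 sep = "-") %in% sim$pairs, ]
    if (!nrow(dist_tab))
      stop("simulate filter selected no (pair, condition) rows", call. = FALSE)
    truth <- ground_truth(
      distances = dist_tab,
      tau_d = sim$tau_d %||% 2.0, noise_level = sim$noise_level %||% 0,
      seed = config$seed)
    out$simulate <- simulate_study(truth, trace_dir,
                                   replicates = sim$replicates %||% 3L)
    out <<- out
  })

  manifest_path <- config$manifest %||% file.path(trace_dir, "manifest.tsv")
  if (any(c("fit_decays", "assign_states", "build_restraints") %in% stages) &&
      !file.exists(manifest_path))
    stop("manifest not found: ", manifest_path,
         " (run the simulate stage or point 'manifest' at existing data)",
         call. = FALSE)

  if ("fit_decays" %in% stages) run_stage("fit_decays", {
    manifest <- utils::read.table(manifest_path, sep = "\t", header = TRUE)
    out$fit_decays <- .stage_fit_decays(manifest, dirname(manifest_path),
                                        registry)
    utils::write.table(out$fit_decays$distances,
                       file.path(config$outdir, "channel_distances.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out <<- out
  })

  if ("assign_states" %in% stages) run_stage("assign_states", {
    records <- .stage_assign(out$fit_decays$distances,
                             config$tolerances$match)
    out$assign_states <- list(records = records,
                              summary = tabulate_conditions(records))
    utils::write.table(out$assign_states$summary,
                       file.path(config$outdir, "state_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(format_state_report(out$assign_states$summary, quiet = TRUE),
               file.path(config$outdir, "state_report.txt"))
    out <<- out
  })

  if ("build_restraints" %in% stages) run_stage("build_restraints", {
    rc <- config$restraints
    summ <- out$assign_states$summary
    recs <- .records_from_summary(summ[summ$condition == rc$condition, ])
    sets <- list()
    for (st in rc$states) {
      set <- suppressWarnings(build_restraints(
        recs, st, chain_map = rc$chain_map,
        bounds_cutoff = config$bounds$cutoff, narrow = config$bounds$narrow,
        wide = config$bounds$wide))
      export_restraint_table(set, path = file.path(
        config$outdir, sprintf("restraints_%s.tbl", st)))
      sets[[st]] <- set
      if (isTRUE(rc$dropouts))
        for (pos in unique(c(set$source_a, set$source_b))) {
          sub <- dropout_subsets(set, pos)
          if (nrow(sub))
            export_restraint_table(sub, path = file.path(
              config$outdir, sprintf("restraints_%s_drop%d.tbl", st, pos)))
        }
    }
    out$build_restraints <- sets
    out <<- out
  })

  if ("validate_models" %in% stages && length(config$models))
    run_stage("validate_models", {
      reports <- list()
      for (st in names(config$models)) {
        if (is.null(out$build_restraints[[st]])) next
        model <- read_model_coordinates(config$models[[st]], model_id = st)
        rep <- validate_model(model, out$build_restraints[[st]],
                              threshold = config$tolerances$validation)
        write_deviation_report(rep, file.path(
          config$outdir, sprintf("deviations_%s.tsv", st)))
        reports[[st]] <- rep
      }
      out$validate_models <- reports
      out <<- out
    })

  if ("saxs_fit" %in% stages && !is.null(config$saxs))
    run_stage("saxs_fit", {
      sx <- config$saxs
      expe <- read_saxs_profile(sx$experimental)
      theo <- lapply(sx$theoretical, read_saxs_profile)
      ranking <- rank_single_states(expe, theo, interpolate = TRUE)
      pop <- fit_populations(expe, theo,
                             n_states = sx$n_states %||% length(theo),
                             interpolate = TRUE)
      lines <- c("single-state ranking (label chi2):",
                 sprintf("  %-20s %.4g", ranking$label, ranking$chi2),
                 sprintf("population fit (%d states, chi2 = %.4g):",
                         pop$n_states, pop$chi2),
                 sprintf("  %-20s %5.1f%%", names(pop$weights),
                         100 * pop$weights))
      writeLines(lines, file.path(config$outdir, "saxs_fit.txt"))
      out$saxs_fit <- list(ranking = ranking, populations = pop)
      out <<- out
    })

  if ("kinetics_fit" %in% stages && !is.null(config$kinetics))
    run_stage("kinetics_fit", {
      fit <- fit_hill_kinetics(read_titration_series(config$kinetics))
      writeLines(utils::capture.output(print(fit)),
                 file.path(config$outdir, "kinetics_fit.txt"))
      out$kinetics_fit <- fit
      out <<- out
    })

  log <- list(seed = config$seed,
              package = as.character(utils::packageVersion("lretstates")),
              r_version = R.version.string,
              stages = stages, finished = format(Sys.time()))
  yaml::write_yaml(log, file.path(config$outdir, "run_log.yaml"))
  invisible(out)
}
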