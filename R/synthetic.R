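# Synthetic-data module: generates every input the pipeline consumes --
# multi-exponential decays through the inverse Forster map, toy bead
# conformers, scattering mixtures and kinetics titrations.

.sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 10007L * as.integer(k)) %% 2147483629L
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Reference conformer-distance table
#'
#' The per-pair, per-condition closed / partially open / open distances
#' (means and replicate SDs, Angstrom) for the Mre11-Rad50 nucleotide-binding
#'-domain complex that the synthetic generator uses as ground truth.  The
#' partially open state carries the two acceptor-channel values separately.
#'
#' @param construct \code{"NBD"} (truncated nucleotide-binding-domain
#'   construct), \code{"FL"} (full-length) or \code{"all"}.
#' @return data.frame with columns \code{residue_a}, \code{residue_b},
#'   \code{construct}, \code{condition}, \code{closed}, \code{closed_sd},
#'   \code{po_bodipy}, \code{po_bodipy_sd}, \code{po_cy3}, \code{po_cy3_sd},
#'   \code{open}, \code{open_sd}.
#' @export
reference_distance_table <- function(construct = c("NBD", "FL", "all")) {
  construct <- match.arg(construct)
  rows <- rbind(
    # residue_a residue_b construct condition closed sd poB sd poC sd open sd
    c(51, 51, "NBD", "apo",        37.5, 0.7, 46.2, 1.3, 46.1, 1.7, 81.4, 2.2),
    c(51, 51, "NBD", "ATP",        37.7, 0.6, 45.4, 1.1, 47.0, 1.0, 78.0, 2.0),
    c(51, 51, "NBD", "ATPgS",      37.9, 0.1, 47.7, 0.4, 48.0, 0.5, 79.1, 1.1),
    c(51, 51, "NBD", "ATP+hairpin",37.7, 1.2, 47.9, 1.4, 47.2, 1.2, 79.1, 1.0),
    c(51, 51, "NBD", "ATP+ssDNA",  36.7, 0.8, 46.8, 1.3, 45.4, 1.4, 74.5, 0.7),
    c(774, 774, "NBD", "apo",        33.7, 0.6, 56.0, 0.3, 50.6, 1.5, 85.0, 1.2),
    c(774, 774, "NBD", "ATP",        35.7, 0.2, 51.5, 2.3, 45.8, 1.8, 83.5, 2.2),
    c(774, 774, "NBD", "ATPgS",      35.6, 0.1, 53.0, 1.5, 48.6, 0.2, 82.6, 3.0),
    c(774, 774, "NBD", "ATP+hairpin",35.4, 0.3, 53.6, 0.5, 46.9, 1.3, 82.7, 2.0),
    c(774, 774, "NBD", "ATP+ssDNA",  35.1, 0.5, 52.8, 0.4, 50.0, 2.7, 75.3, 0.6),
    c(13, 13, "NBD", "apo",        36.7, 1.0, 55.6, 0.3, 46.0, 0.9, 79.9, 2.2),
    c(13, 13, "NBD", "ATP",        35.4, 0.3, 51.1, 1.0, 50.9, 1.1, 77.8, 1.7),
    c(13, 13, "NBD", "ATPgS",      37.1, 0.1, 51.9, 0.1, 47.0, 1.2, 77.1, 0.2),
    c(13, 13, "NBD", "ATP+hairpin",34.4, 1.2, 54.9, 0.8, 47.8, 0.7, 74.9, 0.2),
    c(13, 13, "NBD", "ATP+ssDNA",  34.2, 0.7, 53.9, 0.7, 48.0, 1.7, 75.0, 0.8),
    c(13, 51, "NBD", "apo",        34.7, 0.1, 55.4, 1.0, 50.1, 0.8, 84.1, 1.6),
    c(13, 51, "NBD", "ATP",        36.7, 1.1, 51.4, 0.9, 51.6, 0.3, 79.7, 3.0),
    c(13, 51, "NBD", "ATPgS",      36.0, 0.2, 52.8, 0.2, 51.3, 0.2, 79.7, 1.1),
    c(13, 51, "NBD", "ATP+hairpin",34.7, 0.7, 52.3, 0.4, 50.9, 0.1, 77.2, 0.5),
    c(13, 51, "NBD", "ATP+ssDNA",  35.1, 0.8, 50.0, 0.5, 51.1, 0.4, 74.5, 0.7),
    c(774, 51, "NBD", "apo",        33.0, 0.8, 53.0, 0.8, 48.9, 1.8, 84.0, 0.9),
    c(774, 51, "NBD", "ATP",        30.9, 0.2, 51.5, 0.4, 49.6, 1.5, 80.8, 1.9),
    c(774, 51, "NBD", "ATPgS",      31.2, 0.3, 49.6, 0.6, 47.6, 0.9, 77.8, 0.2),
    c(774, 51, "NBD", "ATP+hairpin",30.6, 0.3, 49.9, 0.9, 51.1, 3.0, 80.9, 0.9),
    c(774, 51, "NBD", "ATP+ssDNA",  30.4, 0.4, 49.6, 0.6, 50.7, 2.1, 75.9, 1.2),
    c(51, 51, "FL", "apo",        35.4, 1.8, 48.7, 0.8, 46.7, 0.6, 75.7, 1.2),
    c(51, 51, "FL", "ATP",        37.3, 0.1, 49.6, 0.2, 46.3, 0.1, 74.7, 0.5),
    c(51, 51, "FL", "ATPgS",      35.3, 0.9, 48.7, 0.5, 46.7, 0.4, 74.4, 1.6),
    c(51, 51, "FL", "ATP+hairpin",34.8, 1.1, 47.7, 0.3, 45.5, 0.4, 72.6, 1.1),
    c(51, 51, "FL", "ATP+ssDNA",  34.9, 1.1, 47.2, 0.4, 45.5, 0.6, 71.0, 0.5),
    c(774, 774, "FL", "apo",        32.8, 0.6, 46.8, 0.6, 48.3, 0.8, 89.0, 3.1),
    c(774, 774, "FL", "ATP",        35.6, 0.3, 50.8, 0.7, 50.5, 0.4, 87.8, 0.7),
    c(774, 774, "FL", "ATPgS",      33.8, 0.3, 46.7, 0.2, 50.1, 0.4, 86.0, 1.5),
    c(774, 774, "FL", "ATP+hairpin",33.6, 0.3, 45.5, 0.6, 46.7, 1.8, 79.9, 1.8),
    c(774, 774, "FL", "ATP+ssDNA",  33.6, 0.2, 45.5, 0.5, 46.7, 1.5, 75.7, 0.8),
    c(13, 13, "FL", "apo",        36.8, 0.3, 51.0, 1.0, 49.6, 0.4, 77.9, 0.6),
    c(13, 13, "FL", "ATP",        36.4, 0.3, 50.9, 0.2, 50.7, 0.2, 79.4, 0.1),
    c(13, 13, "FL", "ATPgS",      35.8, 0.3, 50.8, 0.2, 48.6, 0.7, 76.3, 1.0),
    c(13, 13, "FL", "ATP+hairpin",36.4, 0.6, 51.0, 0.6, 50.4, 0.7, 75.1, 2.1),
    c(13, 13, "FL", "ATP+ssDNA",  36.9, 0.7, 51.3, 1.0, 49.7, 0.2, 75.1, 0.2))
  df <- data.frame(residue_a = as.integer(rows[, 1L]),
                   residue_b = as.integer(rows[, 2L]),
                   construct = rows[, 3L], condition = rows[, 4L])
  num <- apply(rows[, 5:12, drop = FALSE], 2L, as.numeric)
  colnames(num) <- c("closed", "closed_sd", "po_bodipy", "po_bodipy_sd",
                     "po_cy3", "po_cy3_sd", "open", "open_sd")
  df <- cbind(df, num)
  if (construct != "all") df <- df[df$construct == construct, ]
  rownames(df) <- NULL
  df
}

#' Ground truth for a synthetic LRET study
#'
#' Bundles everything the decay generator needs: the per-(pair, condition)
#' state distances, donor lifetimes per probe position, acquisition settings,
#' the instrument-response component, per-channel visibility rules and the
#' noise model.  All randomness downstream flows through \code{seed}.
#'
#' Channel visibility: a state contributes a decay component to a channel
#' only if its transfer efficiency is at least \code{e_min} (weaker transfer
#' is lost in the donor bleed-through; this is what blinds the short-radius
#' Bodipy channel to the open state) and its sensitized lifetime is at least
#' \code{min_lifetime} (faster components are subsumed by the instrument
#' response; this is what blinds the long-radius Cy3 channel to the closed
#' state).
#'
#' @param distances a data.frame in the layout of
#'   [reference_distance_table()] (the default uses its NBD rows).
#' @param tau_d donor-only lifetime (ms): a single default or a named vector
#'   per probe position (names = residue numbers).
#' @param delay,duration,dt acquisition window and sampling interval (ms).
#' @param instrument_tau,instrument_amplitude instrument-response component.
#' @param e_min,min_lifetime channel visibility thresholds (see Details).
#' @param noise_level Gaussian noise scale k in sigma = max(floor, k sqrt(I));
#'   0 for noiseless traces.
#' @param noise_floor sigma floor.
#' @param noise_model \code{"gaussian"} or \code{"poisson"} (photon
#'   counting; \code{noise_level} then scales the counts).
#' @param donor_minor short donor-decay component: list(tau, fraction).
#' @param seed integer seed recorded with the truth.
#' @return A \code{"ground_truth"} object.
#' @export
ground_truth <- function(distances = reference_distance_table("NBD"),
                         tau_d = 2.0, delay = 0.2, duration = 10, dt = 0.01,
                         instrument_tau = 0.05, instrument_amplitude = 0.5,
                         e_min = 0.05, min_lifetime = 0.15,
                         noise_level = 0, noise_floor = 0,
                         noise_model = c("gaussian", "poisson"),
                         donor_minor = list(tau = 0.3, fraction = 0.1),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(is.data.frame(distances), duration > delay, dt > 0)
  st <- as.matrix(distances[c("closed", "po_bodipy", "po_cy3", "open")])
  if (any(st <= 0, na.rm = TRUE)) stop("distances must be positive", call. = FALSE)
  bad <- which(distances$closed >= distances$po_bodipy |
                 pmax(distances$po_bodipy, distances$po_cy3) >= distances$open)
  if (length(bad))
    stop("state distances not ordered closed < partially open < open in row ",
         bad[1L], call. = FALSE)
  structure(list(distances = distances, tau_d = tau_d,
                 acquisition = list(delay = delay, duration = duration,
                                    dt = dt),
                 instrument = list(tau = instrument_tau,
                                   amplitude = instrument_amplitude),
                 visibility = list(e_min = e_min, min_lifetime = min_lifetime),
                 noise = list(model = noise_model, level = noise_level,
                              floor = noise_floor),
                 donor_minor = donor_minor,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

.truth_tau_d <- function(truth, position) {
  td <- truth$tau_d
  if (is.null(names(td))) return(as.numeric(td[1L]))
  val <- td[as.character(position)]
  if (is.na(val))
    stop("no donor lifetime recorded for position ", position, call. = FALSE)
  unname(val)
}

.truth_row <- function(truth, pair, condition) {
  d <- truth$distances
  i <- which(((d$residue_a == pair$residue_a & d$residue_b == pair$residue_b) |
                (d$residue_a == pair$residue_b & d$residue_b == pair$residue_a)) &
               d$condition == condition)
  if (!length(i))
    stop("ground truth covers no pair ", format(pair), " under ", condition,
         call. = FALSE)
  d[i[1L], ]
}

# state distances a channel reports, given the visibility rules
.visible_components <- function(truth, row, channel, pair) {
  reg <- dye_pair_registry()
  dyepair <- if (channel == "bodipy") reg$bodipy else reg$cy3
  dists <- c(closed = row$closed,
             po = if (channel == "bodipy") row$po_bodipy else row$po_cy3,
             open = row$open)
  tau_d <- .truth_tau_d(truth, pair$residue_b)
  e <- 1 / (1 + (dists / dyepair$r0)^6)
  tau_da <- tau_d * (1 - e)
  vis <- e >= truth$visibility$e_min &
    tau_da >= truth$visibility$min_lifetime
  list(states = names(dists)[vis], distances = dists[vis],
       tau_da = tau_da[vis], tau_d = tau_d, pair = dyepair)
}

.apply_noise <- function(intens, noise, seed) {
  if (noise$model == "poisson" && noise$level > 0) {
    return(.with_seed(seed,
                      stats::rpois(length(intens), intens / noise$level) *
                        noise$level))
  }
  if (noise$level <= 0 && noise$floor <= 0) return(intens)
  sd <- pmax(noise$floor, noise$level * sqrt(pmax(intens, 0)))
  .with_seed(seed, intens + stats::rnorm(length(intens), 0, sd))
}

#' Simulate a donor-sensitized acceptor decay from the ground truth
#'
#' Each visible state distance is converted to a sensitized lifetime through
#' the inverse Forster map, the visible states share the physical amplitude
#' equally, an instrument-response component is added, and the decay is
#' sampled on the acquisition window (optionally with noise).
#'
#' @param truth a [ground_truth()].
#' @param pair a [probe_pair()].
#' @param condition condition label present in the truth table.
#' @param channel \code{"bodipy"} or \code{"cy3"}.
#' @param replicate replicate index (enters the noise sub-seed only).
#' @return A [decay_trace()]; the generating components are attached as the
#'   \code{"components"} attribute.
#' @export
simulate_decay <- function(truth, pair, condition,
                           channel = c("bodipy", "cy3"), replicate = 1L) {
  channel <- match.arg(channel)
  stopifnot(inherits(truth, "ground_truth"), inherits(pair, "probe_pair"))
  acq <- truth$acquisition
  if (acq$duration <= acq$delay)
    stop("zero-duration acquisition window", call. = FALSE)
  row <- .truth_row(truth, pair, condition)
  vis <- .visible_components(truth, row, channel, pair)
  if (!length(vis$tau_da))
    stop("no state visible in the ", channel, " channel for pair ",
         format(pair), call. = FALSE)
  times <- seq(acq$delay, acq$duration, by = acq$dt)
  amps <- rep(1 / length(vis$tau_da), length(vis$tau_da))
  taus <- c(truth$instrument$tau, vis$tau_da)
  amps <- c(truth$instrument$amplitude, amps)
  intens <- drop(exp(-outer(times, 1 / taus)) %*% amps)
  k <- pair$residue_a * 7L + pair$residue_b * 13L +
    sum(utf8ToInt(condition)) * 101L +
    match(channel, c("bodipy", "cy3")) * 1009L + replicate * 211L
  intens <- .apply_noise(intens, truth$noise, .sub_seed(truth$seed, k))
  tr <- decay_trace(times, intens, channel = channel, delay = acq$delay,
                    metadata = list(pair = format(pair),
                                    condition = condition,
                                    replicate = replicate))
  attr(tr, "components") <- data.frame(state = c("instrument", vis$states),
                                       amplitude = amps, lifetime = taus)
  tr
}

#' @rdname simulate_decay
#' @param position probe residue number (donor-only sample).
#' @export
simulate_donor_decay <- function(truth, position, replicate = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  acq <- truth$acquisition
  tau_d <- .truth_tau_d(truth, position)
  times <- seq(acq$delay, acq$duration, by = acq$dt)
  fr <- truth$donor_minor$fraction
  taus <- c(truth$donor_minor$tau, tau_d)
  amps <- c(fr, 1 - fr)
  intens <- drop(exp(-outer(times, 1 / taus)) %*% amps)
  k <- position * 17L + replicate * 977L + 31L
  intens <- .apply_noise(intens, truth$noise, .sub_seed(truth$seed, k))
  decay_trace(times, intens, channel = "donor", delay = acq$delay,
              metadata = list(position = position, replicate = replicate))
}

#' Simulate a full study: trace files plus a manifest
#'
#' Writes one decay file per (pair, condition, channel, replicate), plus
#' donor-only traces per probe position and replicate, and a tab-separated
#' manifest mapping files to their metadata.  Deterministic given the truth
#' seed: rerunning with the same truth yields byte-identical files.
#'
#' @param truth a [ground_truth()].
#' @param dir output directory (created if needed).
#' @param replicates replicate count (default 3).
#' @return The manifest data.frame (invisibly); written to
#'   \code{dir/manifest.tsv}.
#' @export
simulate_study <- function(truth, dir, replicates = 3L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (replicates < 1L) stop("'replicates' must be >= 1", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- truth$distances
  rows <- list()
  for (i in seq_len(nrow(d))) {
    pr <- probe_pair(d$residue_a[i], d$residue_b[i])
    for (ch in c("bodipy", "cy3")) for (r in seq_len(replicates)) {
      tr <- simulate_decay(truth, pr, d$condition[i], ch, r)
      fn <- sprintf("trace_%s_%s_%s_r%d.txt", format(pr),
                    gsub("[^A-Za-z0-9]", "", d$condition[i]), ch, r)
      write_decay_trace(tr, file.path(dir, fn))
      rows[[length(rows) + 1L]] <-
        data.frame(file = fn, residue_a = pr$residue_a,
                   residue_b = pr$residue_b, channel = ch,
                   condition = d$condition[i], replicate = r)
    }
  }
  for (pos in unique(c(d$residue_a, d$residue_b)))
    for (r in seq_len(replicates)) {
      tr <- simulate_donor_decay(truth, pos, r)
      fn <- sprintf("donor_%d_r%d.txt", pos, r)
      write_decay_trace(tr, file.path(dir, fn))
      rows[[length(rows) + 1L]] <-
        data.frame(file = fn, residue_a = pos, residue_b = pos,
                   channel = "donor", condition = "donor-only", replicate = r)
    }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

# deterministic quasi-uniform directions on the sphere (Fibonacci lattice)
.fib_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Build toy two-protomer bead conformers matching target probe distances
#'
#' Places two rigid protomer copies related by a two-fold (C2) rotation
#' about the z axis so that every requested inter-protomer probe distance is
#' met: protomer A probe i at \eqn{(x_i, y_i, z_i)}, protomer B probe at
#' \eqn{(-x_i, -y_i, z_i)}.  Identity-pair targets have the closed form
#' \eqn{x_i = d_i/2}; general cross-pair targets are solved by least
#' squares, and a geometrically infeasible target set (e.g. one violating a
#' triangle inequality among the probe separations) raises a feasibility
#' error reporting the worst-violated restraint.  Each protomer is fleshed
#' out with a deterministic cloud of body beads rigidly attached to its
#' probe centroid, so different states produce genuinely different
#' scattering profiles.
#'
#' @param distances named list: state label -> either a named numeric vector
#'   of identity-pair distances (names = residue numbers) or a data.frame
#'   with columns \code{residue_a}, \code{residue_b}, \code{distance}.
#' @param spread z spacing between successive probes on a protomer (A).
#' @param body_beads number of body beads per protomer (0 to disable).
#' @param body_radius radius of the body-bead cloud (A).
#' @param tol maximum allowed |achieved - target| (A) before a feasibility
#'   error is raised.
#' @param pdb_dir optional directory: writes one PDB per state for the
#'   file-based validation path.
#' @return Named list (one entry per state) of
#'   \code{list(beads = bead_model, model = model_coordinates,
#'   achieved = data.frame)}.
#' @export
build_toy_conformers <- function(distances, spread = 10, body_beads = 40L,
                                 body_radius = 15, tol = 1e-6,
                                 pdb_dir = NULL) {
  stopifnot(is.list(distances), length(distances) >= 1L)
  out <- list()
  for (state in names(distances)) {
    tg <- distances[[state]]
    if (is.numeric(tg) && !is.null(names(tg)))
      tg <- data.frame(residue_a = as.integer(names(tg)),
                       residue_b = as.integer(names(tg)),
                       distance = as.numeric(tg))
    stopifnot(all(c("residue_a", "residue_b", "distance") %in% names(tg)))
    probes <- sort(unique(c(tg$residue_a, tg$residue_b)))
    k <- length(probes)
    ia <- match(tg$residue_a, probes); ib <- match(tg$residue_b, probes)
    cross_d <- function(P) {          # P: k x 3 coords of protomer A probes
      sqrt((P[ia, 1L] + P[ib, 1L])^2 + (P[ia, 2L] + P[ib, 2L])^2 +
             (P[ia, 3L] - P[ib, 3L])^2)
    }
    # start: identity-pair closed form, probes stacked along z
    x0 <- vapply(probes, function(p) {
      i <- which(tg$residue_a == p & tg$residue_b == p)
      if (length(i)) tg$distance[i[1L]] / 2 else mean(tg$distance) / 2
    }, numeric(1))
    P0 <- cbind(x0, 0, spread * (seq_len(k) - 1L))
    obj <- function(par) sum((cross_d(matrix(par, k)) - tg$distance)^2)
    best <- list(par = as.numeric(P0), value = obj(as.numeric(P0)))
    if (best$value > tol^2) {
      for (s in 1:6) {
        start <- .with_seed(1000L + s,
                            as.numeric(P0) + stats::rnorm(3L * k, 0, spread))
        op <- stats::optim(start, obj, method = "BFGS",
                           control = list(maxit = 2000L, reltol = 1e-15))
        op <- stats::optim(op$par, obj, method = "BFGS",
                           control = list(maxit = 2000L, reltol = 1e-15))
        if (op$value < best$value) best <- op
        if (best$value < tol^2 / 4) break
      }
    }
    P <- matrix(best$par, k)
    achieved <- cross_d(P)
    viol <- abs(achieved - tg$distance)
    if (max(viol) > tol) {
      w <- which.max(viol)
      stop(sprintf(paste0("infeasible distance targets for state '%s': pair ",
                          "%d-%d wants %.2f A but the best embedding gives ",
                          "%.2f A (check the triangle inequalities among ",
                          "the probe separations)"), state, tg$residue_a[w],
                   tg$residue_b[w], tg$distance[w], achieved[w]),
           call. = FALSE)
    }
    B <- cbind(-P[, 1L], -P[, 2L], P[, 3L])
    coords <- data.frame(chain = rep(c("A", "B"), each = k),
                         residue = rep(probes, 2L),
                         x = c(P[, 1L], B[, 1L]), y = c(P[, 2L], B[, 2L]),
                         z = c(P[, 3L], B[, 3L]))
    model <- model_coordinates(coords, model_id = state)
    pos <- as.matrix(coords[c("x", "y", "z")])
    if (body_beads > 0L) {
      cloud <- .fib_sphere(body_beads, body_radius)
      cA <- sweep(cloud, 2L, colMeans(P), `+`)
      cB <- cbind(-cA[, 1L], -cA[, 2L], cA[, 3L])
      pos <- rbind(pos, cA, cB)
    }
    out[[state]] <- list(beads = bead_model(pos, label = state),
                         model = model,
                         achieved = data.frame(tg, achieved = achieved))
    if (!is.null(pdb_dir)) {
      dir.create(pdb_dir, showWarnings = FALSE, recursive = TRUE)
      write_model_pdb(model, file.path(pdb_dir, paste0(state, ".pdb")))
    }
  }
  out
}

#' Simulate a multi-state scattering mixture
#'
#' Computes \eqn{c \sum_k w_k I_k(q)} from the state profiles (or bead
#' models) and attaches a sigma column of \code{sigma_frac} times the
#' intensity; with \code{noise > 0}, seeded Gaussian noise of that relative
#' magnitude is added and sigma reflects it.
#'
#' @param states list of \code{"saxs_profile"}s or \code{"bead_model"}s.
#' @param weights state weights on the simplex (nonnegative, summing to 1).
#' @param q_grid q grid (1/A); required when \code{states} are bead models.
#' @param noise relative Gaussian noise level (0 = noiseless).
#' @param seed RNG seed for the noise.
#' @param scale global scale factor c.
#' @param sigma_frac nominal relative uncertainty recorded when noiseless.
#' @return A \code{"saxs_profile"} with sigmas.
#' @export
simulate_saxs_mixture <- function(states, weights, q_grid = NULL, noise = 0,
                                  seed = NULL, scale = 1, sigma_frac = 0.01) {
  weights <- as.numeric(weights)
  if (length(states) != length(weights))
    stop("'states' and 'weights' lengths differ", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must be nonnegative and sum to 1", call. = FALSE)
  profiles <- lapply(states, function(s) {
    if (inherits(s, "bead_model")) {
      if (is.null(q_grid))
        stop("'q_grid' required when states are bead models", call. = FALSE)
      debye_profile(s, q_grid)
    } else s
  })
  q <- profiles[[1L]]$q
  iy <- scale * Reduce(`+`, Map(function(p, w) w * p$intensity,
                                profiles, weights))
  rel <- max(noise, sigma_frac)
  sigma <- rel * pmax(iy, 1e-12)
  if (noise > 0)
    iy <- .with_seed(seed, iy + stats::rnorm(length(iy), 0, noise * iy))
  saxs_profile(q, iy, sigma = sigma, label = "mixture")
}

#' Simulate a Hill-kinetics titration
#'
#' @param vmax,km,n Hill parameters (pmol/min, uM, unitless).
#' @param concentrations substrate concentrations (uM), increasing.
#' @param noise Gaussian noise SD as a fraction of vmax (0 = noiseless).
#' @param seed RNG seed.
#' @return A [titration_series()].
#' @export
simulate_titration <- function(vmax, km, n, concentrations, noise = 0,
                               seed = NULL) {
  if (!length(concentrations)) stop("empty concentration list", call. = FALSE)
  v <- vmax * concentrations^n / (km^n + concentrations^n)
  if (noise > 0)
    v <- .with_seed(seed, v + stats::rnorm(length(v), 0, noise * vmax))
  titration_series(concentrations, v)
}
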