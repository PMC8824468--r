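test_that("reference distance table is complete and state-ordered", {
  nbd <- reference_distance_table("NBD")
  expect_equal(nrow(nbd), 25L)
  expect_equal(nrow(reference_distance_table("FL")), 15L)
  expect_equal(nrow(reference_distance_table("all")), 40L)
  expect_true(all(nbd$closed < pmin(nbd$po_bodipy, nbd$po_cy3)))
  expect_true(all(pmax(nbd$po_bodipy, nbd$po_cy3) < nbd$open))
  expect_setequal(unique(nbd$condition),
                  c("apo", "ATP", "ATPgS", "ATP+hairpin", "ATP+ssDNA"))
})

test_that("channel visibility reproduces the short/long acceptor asymmetry", {
  truth <- noiseless_truth()
  nbd <- truth$distances
  for (i in seq_len(nrow(nbd))) {
    pr <- probe_pair(nbd$residue_a[i], nbd$residue_b[i])
    bod <- attr(simulate_decay(truth, pr, nbd$condition[i], "bodipy"),
                "components")
    cy <- attr(simulate_decay(truth, pr, nbd$condition[i], "cy3"),
               "components")
    # Bodipy reports closed + partially open, never open
    expect_setequal(bod$state, c("instrument", "closed", "po"))
    # Cy3 reports partially open + open, never closed
    expect_setequal(cy$state, c("instrument", "po", "open"))
  }
})

test_that("simulated decay components invert to the generating distances", {
  truth <- noiseless_truth()
  pr <- probe_pair(51)
  tr <- simulate_decay(truth, pr, "ATP", "cy3")
  comp <- attr(tr, "components")
  phys <- comp[comp$state != "instrument", ]
  back <- vapply(phys$lifetime, function(tau)
    distance_from_lifetimes(tau, 2.0, tb_cy3)$mean, numeric(1))
  expect_equal(sort(back), c(47.0, 78.0), tolerance = 1e-9)
  expect_error(simulate_decay(truth, probe_pair(999), "ATP", "cy3"),
               "covers no pair")
  expect_error(ground_truth(duration = 0.1), "duration")
})

test_that("donor-only decays obey the configured amplitude split", {
  truth <- noiseless_truth()
  tr <- simulate_donor_decay(truth, 51)
  res <- fit_donor_lifetime(tr)
  expect_equal(res$tau_d, 2.0, tolerance = 1e-5)
  expect_equal(res$amplitude_fraction, 0.9, tolerance = 1e-3)
})

test_that("ground truth rejects unordered or non-positive distances", {
  bad <- reference_distance_table("NBD")
  bad$closed[3] <- bad$open[3] + 1
  expect_error(ground_truth(distances = bad), "ordered")
  bad2 <- reference_distance_table("NBD")
  bad2$po_cy3[1] <- -2
  expect_error(ground_truth(distances = bad2), "positive|ordered")
})

test_that("a simulated study writes the expected file census deterministically", {
  sub <- reference_distance_table("NBD")
  sub <- sub[sub$condition %in% c("apo", "ATP") &
               paste(sub$residue_a, sub$residue_b) %in% c("51 51", "13 13"), ]
  truth <- ground_truth(distances = sub, noise_level = 0.01, seed = 7L)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- simulate_study(truth, d1, replicates = 2L)
  # 4 rows x 2 channels x 2 replicates + 2 donor positions x 2 replicates
  expect_equal(nrow(m1), 4L * 2L * 2L + 2L * 2L)
  expect_true(file.exists(file.path(d1, "manifest.tsv")))
  expect_true(all(file.exists(file.path(d1, m1$file))))
  # byte-identical rerun under the same seed, even with noise on
  simulate_study(truth, d2, replicates = 2L)
  for (f in m1$file)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  expect_error(simulate_study(truth, tempfile(), replicates = 0L), ">= 1")
})

test_that("full circle: noiseless simulation reproduces every truth distance", {
  truth <- noiseless_truth()
  nbd <- truth$distances
  for (i in seq_len(nrow(nbd))) {
    pr <- probe_pair(nbd$residue_a[i], nbd$residue_b[i])
    rec <- suppressWarnings(
      recover_conformers(truth, pr, nbd$condition[i], match_tolerance = 6))
    expect_equal(rec$case_label, 1L)
    expect_equal(rec$closed$mean, nbd$closed[i], tolerance = 0.5 / 35)
    expect_equal(rec$partially_open_bodipy$mean, nbd$po_bodipy[i],
                 tolerance = 0.5 / 45)
    expect_equal(rec$partially_open_cy3$mean, nbd$po_cy3[i],
                 tolerance = 0.5 / 45)
    expect_equal(rec$open$mean, nbd$open[i], tolerance = 0.5 / 75)
  }
})

test_that("noisy recovery stays within the replicate scatter", {
  truth <- ground_truth(noise_level = 0.002, seed = 13L)
  pr <- probe_pair(51)
  recs <- lapply(1:3, function(r)
    suppressWarnings(recover_conformers(truth, pr, "ATP", replicate = r,
                                        match_tolerance = 6)))
  tab <- tabulate_conditions(recs)
  closed <- tab[tab$state == "closed", ]
  expect_lt(abs(closed$mean - 37.7), 2 * max(closed$sd, 0.25))
  open <- tab[tab$state == "open", ]
  expect_lt(abs(open$mean - 78.0), 2 * max(open$sd, 1))
})

test_that("toy conformers hit their targets and detect infeasible geometry", {
  conf <- build_toy_conformers(toy_targets())
  expect_named(conf, c("closed", "partially_open", "open"))
  for (s in conf) {
    expect_lt(max(abs(s$achieved$achieved - s$achieved$distance)), 1e-6)
    expect_s3_class(s$beads, "bead_model")
    expect_gt(nrow(s$beads$positions), 6L)  # probes + body beads
  }
  # cross-pair targets solved too
  mixed <- build_toy_conformers(list(closed = data.frame(
    residue_a = c(13, 51, 13), residue_b = c(13, 51, 51),
    distance = c(35.4, 37.7, 36.7))))
  expect_lt(max(abs(mixed$closed$achieved$achieved -
                      mixed$closed$achieved$distance)), 1e-6)
  # mutually contradictory crosses violate the triangle inequalities
  infeasible <- list(bad = data.frame(
    residue_a = c(1, 2, 3, 1, 1, 2), residue_b = c(1, 2, 3, 2, 3, 3),
    distance = c(60, 60, 60, 1, 1, 1)))
  expect_error(build_toy_conformers(infeasible), "infeasible")
  # PDB emission for the validation path
  pd <- tempfile()
  build_toy_conformers(toy_targets()["open"], pdb_dir = pd)
  expect_true(file.exists(file.path(pd, "open.pdb")))
})

test_that("scattering mixtures respect the simplex and seeding", {
  conf <- build_toy_conformers(toy_targets()[c("closed", "open")])
  q <- toy_q_grid(60)
  profs <- lapply(conf, function(s) debye_profile(s$beads, q))
  expect_error(simulate_saxs_mixture(profs, c(0.7, 0.2)), "sum to 1")
  expect_error(simulate_saxs_mixture(profs, c(1.2, -0.2)), "nonnegative")
  pure <- simulate_saxs_mixture(profs, c(1, 0))
  expect_equal(pure$intensity, profs$closed$intensity, tolerance = 1e-12)
  n1 <- simulate_saxs_mixture(profs, c(0.6, 0.4), noise = 0.02, seed = 4)
  n2 <- simulate_saxs_mixture(profs, c(0.6, 0.4), noise = 0.02, seed = 4)
  expect_identical(n1$intensity, n2$intensity)
})

test_that("titration simulation honors the half-max identity and seeds", {
  ts <- simulate_titration(100, 50, 1, seq(10, 300, by = 10))
  expect_equal(ts$rates[ts$concentrations == 50], 50)
  expect_error(simulate_titration(100, 50, 1, numeric(0)), "empty")
  a <- simulate_titration(100, 50, 2, c(10, 50, 100), noise = 0.05, seed = 2)
  b <- simulate_titration(100, 50, 2, c(10, 50, 100), noise = 0.05, seed = 2)
  expect_identical(a$rates, b$rates)
})
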