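# helpers building small restraint sets from assigned records
closed_recs <- function() list(
  assign_states(c(37.7, 45.4), c(47.0, 78.0), probe_pair(51), "ATP"),
  assign_states(c(35.4, 51.1), c(50.9, 77.8), probe_pair(13), "ATP"),
  assign_states(c(36.7, 51.4), c(51.6, 79.7), probe_pair(13, 51), "ATP"))

test_that("bounds follow the 75-Angstrom rule with an inclusive boundary", {
  rec <- assign_states(c(37.7, 45.4), c(47.0, 78.0), probe_pair(51), "ATP")
  closed <- build_restraints(list(rec), "closed")
  expect_equal(nrow(closed), 1L)
  expect_equal(closed$target, 37.7)
  expect_equal(c(closed$minus, closed$plus), c(5, 5))
  expect_equal(closed$target - closed$minus, 32.7)
  expect_equal(closed$target + closed$plus, 42.7)
  open <- build_restraints(list(rec), "open")
  expect_equal(c(open$minus, open$plus), c(7, 7))
  # boundary: exactly 75 A stays narrow ("greater than 75" widens)
  rec75 <- assign_states(numeric(0), c(50, 75), probe_pair(93), "ATP",
                         state_map = list(short = "partially_open_cy3",
                                          long = "open"))
  r75 <- build_restraints(list(rec75), "open")
  expect_equal(c(r75$minus, r75$plus), c(5, 5))
})

test_that("mixed pairs are duplicated symmetrically, identity pairs are not", {
  rec <- assign_states(c(36.7, 51.4), c(51.6, 79.7), probe_pair(13, 51), "ATP")
  set <- build_restraints(list(rec), "open")
  expect_equal(nrow(set), 2L)
  # the mirrored restraint exists with identical target and bounds
  i <- which(set$residue_a == 13)
  j <- which(set$residue_a == 51)
  expect_equal(set$residue_b[i], 51)
  expect_equal(set$residue_b[j], 13)
  expect_equal(set$target[i], set$target[j])
  expect_equal(set$minus[i], set$minus[j])
  expect_equal(set$target[i], 79.7)
})

test_that("mirror-symmetry and bounds-width invariants hold on built sets", {
  for (state in c("closed", "partially_open", "open")) {
    set <- build_restraints(closed_recs(), state)
    # width invariant: 10 A at or below the cutoff, 14 A above
    width <- set$minus + set$plus
    expect_true(all(width == ifelse(set$target > 75, 14, 10)))
    # mirror invariant for every hetero restraint
    for (i in seq_len(nrow(set))) {
      if (set$residue_a[i] == set$residue_b[i]) next
      m <- which(set$residue_a == set$residue_b[i] &
                   set$residue_b == set$residue_a[i] &
                   set$target == set$target[i])
      expect_gte(length(m), 1L)
    }
  }
})

test_that("partially open restraints use the channel mean or both values", {
  recs <- closed_recs()[1]
  mean_set <- build_restraints(recs, "partially_open")
  expect_equal(mean_set$target, mean(c(45.4, 47.0)))
  both <- build_restraints(recs, "partially_open", partially_open = "both")
  expect_equal(sort(both$target), c(45.4, 47.0))
})

test_that("missing states skip with a warning, or error in strict mode", {
  rec4 <- assign_states(numeric(0), c(50, 80), probe_pair(93), "ATP")
  expect_warning(set <- build_restraints(c(closed_recs(), list(rec4)),
                                         "closed"), "absent")
  expect_equal(nrow(set), 4L)
  expect_error(suppressWarnings(
    build_restraints(list(rec4), "closed", strict = TRUE)), "absent")
  expect_error(suppressWarnings(build_restraints(list(rec4), "closed")),
               "no restraints")
})

test_that("restraint export round-trips exactly through the assign dialect", {
  set <- build_restraints(closed_recs(), "open")
  lines <- export_restraint_table(set)
  expect_length(lines, nrow(set))
  expect_match(lines, "^assign \\(segid A and resid \\d+ and name CB\\)",
               all = TRUE)
  back <- read_restraint_table(text = lines)
  for (col in c("segment_a", "residue_a", "segment_b", "residue_b", "atom",
                "target", "minus", "plus", "state", "source_a", "source_b"))
    expect_equal(back[[col]], set[[col]], info = col)
  # write/read through a file, with pass-through appended lines preserved
  f <- tempfile(fileext = ".tbl"); air <- tempfile()
  writeLines("! ambiguous interface restraints appended verbatim", air)
  export_restraint_table(set, path = f, append_file = air)
  expect_equal(readLines(f)[nrow(set) + 1L],
               "! ambiguous interface restraints appended verbatim")
  expect_equal(read_restraint_table(f)$target, set$target)
  expect_error(export_restraint_table(set, dialect = "xplor"), "dialect")
})

test_that("dropout removes every restraint touching a probe position", {
  set <- build_restraints(closed_recs(), "open")   # pairs 51-51, 13-13, 13-51
  sub <- dropout_subsets(set, 51)
  expect_true(all(sub$source_a != 51 & sub$source_b != 51))
  expect_equal(unique(c(sub$source_a, sub$source_b)), 13)
  expect_warning(same <- dropout_subsets(set, 999), "no restraint")
  expect_equal(nrow(same), nrow(set))
  # sequentially dropping all probe positions empties the set
  empty <- dropout_subsets(dropout_subsets(set, 51), 13)
  expect_equal(nrow(empty), 0L)
})

test_that("models built on the restraint targets validate perfectly", {
  conf <- build_toy_conformers(toy_targets())
  recs <- list(
    assign_states(c(35.4, 51.1), c(50.9, 77.8), probe_pair(13), "ATP"),
    assign_states(c(37.7, 46.2), c(46.2, 78.0), probe_pair(51), "ATP"),
    assign_states(c(35.7, 48.65), c(48.65, 83.5), probe_pair(774), "ATP"))
  set <- build_restraints(recs, "closed")
  rep <- validate_model(conf$closed$model, set, threshold = 5)
  s <- attr(rep, "summary")
  expect_equal(s$n_satisfied, s$n_total)
  expect_lt(s$max_abs_deviation, 1e-6)
  # the contrasting state's model fails everywhere at the same threshold
  rep_open <- validate_model(conf$open$model, set, threshold = 5)
  expect_equal(attr(rep_open, "summary")$n_satisfied, 0L)
  # a model missing a restrained chain errors by name
  half <- conf$closed$model
  half$coords <- half$coords[half$coords$chain == "A", ]
  expect_error(validate_model(half, set), "chain B")
})

test_that("a single displaced residue breaks exactly one identity restraint", {
  conf <- build_toy_conformers(toy_targets())
  recs <- list(
    assign_states(c(35.4, 51.1), c(50.9, 77.8), probe_pair(13), "ATP"),
    assign_states(c(37.7, 46.2), c(46.2, 78.0), probe_pair(51), "ATP"))
  set <- build_restraints(recs, "closed")
  model <- conf$closed$model
  i <- which(model$coords$chain == "A" & model$coords$residue == 13)
  j <- which(model$coords$chain == "B" & model$coords$residue == 13)
  axis <- as.numeric(model$coords[i, c("x", "y", "z")] -
                       model$coords[j, c("x", "y", "z")])
  axis <- axis / sqrt(sum(axis^2))
  model$coords[i, c("x", "y", "z")] <-
    model$coords[i, c("x", "y", "z")] + 8 * axis
  rep <- validate_model(model, set, threshold = 5)
  expect_equal(attr(rep, "summary")$n_satisfied, nrow(set) - 1L)
  expect_false(rep$satisfied[rep$residue_a == 13])
  expect_equal(rep$deviation[rep$residue_a == 13], 8, tolerance = 1e-9)
})

test_that("PDB write/read preserves restrained-atom geometry", {
  conf <- build_toy_conformers(toy_targets()["closed"])
  f <- tempfile(fileext = ".pdb")
  write_model_pdb(conf$closed$model, f)
  back <- read_model_coordinates(f)
  recs <- list(assign_states(c(35.4, 51.1), c(50.9, 77.8), probe_pair(13),
                             "ATP"))
  set <- build_restraints(recs, "closed")
  rep <- validate_model(back, set, threshold = 5)
  expect_equal(attr(rep, "summary")$max_abs_deviation, 0, tolerance = 1e-3)
})

test_that("cluster consistency reports per-pair SDs across cluster models", {
  conf <- build_toy_conformers(toy_targets())
  recs <- list(assign_states(c(35.4, 51.1), c(50.9, 77.8), probe_pair(13),
                             "ATP"),
               assign_states(c(37.7, 46.2), c(46.2, 78.0), probe_pair(51),
                             "ATP"))
  set <- build_restraints(recs, "closed")
  # identical models in three clusters: zero spread
  res <- cluster_consistency(rep(list(conf$closed$model), 3L), set)
  expect_equal(res$average_sd, 0)
  # constructed spread {40, 41, 42} -> SD exactly 1
  models <- lapply(c(40, 41, 42) / 35.4, function(f) {
    m <- conf$closed$model
    m$coords[c("x", "y", "z")] <- m$coords[c("x", "y", "z")] * f
    m
  })
  res2 <- cluster_consistency(models, set[set$residue_a == 13, ])
  expect_equal(res2$per_pair$sd, 1, tolerance = 1e-9)
  expect_error(cluster_consistency(list(conf$closed$model), set), "two")
})
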