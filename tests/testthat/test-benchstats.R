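test_that("loop_fraction is the share of none/turn/bend residues", {
  coil <- assign_secstruct(structure_from_backbone(
    make_ideal_segment("coil", 15, seed = 2), "c"))
  expect_equal(loop_fraction(coil), 1.0)
  helix <- assign_secstruct(structure_from_backbone(
    make_ideal_segment("alpha_helix", 12), "h"))
  expect_equal(loop_fraction(helix), mean(helix$loop))
  expect_lt(loop_fraction(helix), 0.5)
})

test_that("length stratification reports mean, standard error and ordering", {
  rows <- data.frame(pair_id = letters[1:5], length = c(5, 5, 7, 3, 3),
                     rmsd = c(0.2, 0.4, 1.0, 0.1, 0.3))
  s <- stratify_by_length(rows, "rmsd")
  expect_equal(s$length, c(3, 5, 7))               # ascending
  r5 <- s[s$length == 5, ]
  expect_equal(r5$mean, 0.3)
  expect_equal(r5$se, sd(c(0.2, 0.4)) / sqrt(2))   # 0.1
  expect_equal(r5$se, 0.1)
  expect_equal(s$se[s$length == 7], 0)             # singleton convention
  expect_equal(sum(s$n), nrow(rows))
  expect_error(stratify_by_length(rows, "nope"), "unknown")
})

test_that("linear_fit reproduces closed-form OLS and its conventions", {
  f <- linear_fit(1:10, 2 * (1:10) + 1)
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  # hand-computed OLS for x = 1,2,3; y = 1,3,2
  f2 <- linear_fit(c(1, 2, 3), c(1, 3, 2))
  expect_equal(f2$slope, 0.5)
  expect_equal(f2$intercept, 1.0)
  expect_equal(f2$r_squared, 0.25)
  expect_equal(linear_fit(1:5, rep(2, 5))$r_squared, 0)
  expect_error(linear_fit(rep(1, 4), 1:4), "distinct")
})

test_that("composition tables normalise to 1 and split sheets by sense", {
  cls <- c("C", "C", "T", "T", "H")
  comp <- sse_composition(cls)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-9)
  expect_equal(comp$fraction[comp$category == "none"], 0.4)
  expect_equal(comp$fraction[comp$category == "turn"], 0.4)
  expect_equal(comp$fraction[comp$category == "alpha_helix"], 0.2)
  expect_equal(attr(comp, "regular_fraction"), 0.2)
  expect_equal(attr(comp, "helix_share"), 1)
  comp2 <- sse_composition(c("E", "E", "B", "C"), c("P", "A", "A", ""))
  expect_equal(comp2$fraction[comp2$category == "parallel_sheet"], 0.25)
  expect_equal(comp2$fraction[comp2$category == "antiparallel_sheet"], 0.5)
})

test_that("representatives are the loops closest to their length mean", {
  rows <- data.frame(pair_id = c("a", "b", "c", "d", "e"),
                     length = c(5, 5, 5, 8, 9),
                     rmsd = c(0.1, 0.3, 0.5, 0.7, 0.2))
  rep5 <- select_representatives(rows, 5)
  expect_equal(rep5$pair_id, "b")      # mean 0.3, exact hit
  expect_equal(select_representatives(rows, 8)$pair_id, "d")  # singleton
  # tie at equal distance breaks to the smaller pair_id
  rows2 <- data.frame(pair_id = c("x", "a"), length = 4, rmsd = c(0.2, 0.4))
  expect_equal(select_representatives(rows2, 4)$pair_id, "a")
  expect_warning(select_representatives(rows, 99), "skipped")
})

test_that("ensemble variability counts pairs and honours identity cases", {
  bp <- build_protein(synthetic_spec(seed = 71, protein_length_range = c(80, 100)),
                      seed = 71, id = "ens")
  ref <- bp$structure
  reps <- make_ensemble_replicates(ref, n_rep = 2, sigma = 0.33, seed = 5)
  exps <- c(list(ref), reps)
  pred <- ref
  pred$source <- "predicted"; pred$id <- "ens_pred"
  ev <- ensemble_variability(exps, pred)
  n_loops <- length(unique(ev$exp_exp$pair_id))
  expect_equal(nrow(ev$exp_exp), 3 * n_loops)          # k(k-1)/2 = 3 per loop
  # prediction identical to the reference copy contributes zero RMSDs
  expect_true(any(ev$pred_exp$rmsd < 1e-8))
  expect_gt(ev$mean_exp_exp, 0)
  expect_error(ensemble_variability(list(ref), pred), "at least 2")
  # identical replicates give an all-zero experimental range
  ev2 <- ensemble_variability(list(ref, ref), pred)
  expect_equal(max(ev2$exp_exp$rmsd), 0, tolerance = 1e-8)
})

test_that("correlation and binning follow their closed forms", {
  expect_equal(correlate(1:10, 1:10)$r, 1)
  expect_equal(correlate(1:10, -(1:10))$r, -1)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate(x, y)$r, r_direct)
  expect_equal(correlate(x, y)$r_squared, r_direct^2)
  expect_warning(cc <- correlate(rep(1, 5), 1:5), "variance")
  expect_true(is.na(cc$r))
  b <- binned_profile(c(0.12, 0.14, 0.31), c(10, 20, 50), width = 0.1)
  expect_equal(b$n, c(2L, 1L))
  expect_equal(b$mean, c(15, 50))
  expect_equal(b$min[1], 10); expect_equal(b$max[1], 20)
})

test_that("hydropathy uses the Kyte-Doolittle scale", {
  expect_equal(hydropathy_index("IIII"), 4.5)
  expect_equal(hydropathy_index("RRR"), -4.5)
  expect_equal(hydropathy_index("IR"), 0)
  expect_message(v <- hydropathy_index("IXR"), "nonstandard")
  expect_equal(v, 0)
})
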