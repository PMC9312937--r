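test_that("ideal segments have plausible backbone geometry and classes", {
  for (kind in c("alpha_helix", "beta_strand", "coil")) {
    bb <- make_ideal_segment(kind, 10, seed = 3)
    ca_ca <- sqrt(rowSums((bb$CA[-1, ] - bb$CA[-10, ])^2))
    expect_true(all(abs(ca_ca - 3.8) < 0.15))
  }
  coil <- assign_secstruct(structure_from_backbone(
    make_ideal_segment("coil", 8, seed = 11), "c8"))
  expect_false(any(coil$class8 %in% c("H", "E")))
  one <- make_ideal_segment("coil", 1, seed = 1)
  expect_equal(nrow(one$CA), 1L)
})

test_that("build_protein is deterministic and honours extreme loop fractions", {
  spec <- synthetic_spec(seed = 1, protein_length_range = c(80, 120))
  a <- build_protein(spec, seed = 7, id = "x")
  b <- build_protein(spec, seed = 7, id = "x")
  expect_identical(a$structure$atoms, b$structure$atoms)
  allcoil <- build_protein(synthetic_spec(target_loop_fraction = 1,
                                          protein_length_range = c(60, 80)),
                           seed = 3, id = "coily")
  expect_equal(loop_fraction(assign_secstruct(allcoil$structure)), 1.0)
})

test_that("loop lengths follow the calibrated short-dominated law", {
  spec <- synthetic_spec(n_proteins = 40, seed = 515,
                         protein_length_range = c(100, 200))
  bm <- simulate_benchmark(spec)
  tr <- bm$truth[bm$truth$length >= 3, ]
  expect_gt(nrow(tr), 300)
  expect_lt(abs(mean(tr$length < 10) - 0.827), 0.05)
  expect_gt(mean(tr$length < 20), 0.93)
})

test_that("zero noise and zero injection reproduce the experimental loops exactly", {
  spec <- synthetic_spec(n_proteins = 2, seed = 9,
                         protein_length_range = c(80, 120),
                         noise_sigma = function(L) 0,
                         sse_noise = 0,
                         helix_injection_rate = function(L) 0)
  bm <- simulate_benchmark(spec)
  b <- run_benchmark(bm)
  expect_true(all(b$metrics$rmsd < 1e-8))
  expect_true(all(abs(b$metrics$tm - 1) < 1e-8))
  expect_true(all(b$metrics$delta_sse == 0))
})

test_that("forced injection creates regular structure in the prediction", {
  spec <- synthetic_spec(n_proteins = 1, seed = 13,
                         protein_length_range = c(120, 160),
                         noise_sigma = function(L) 0.05,
                         helix_injection_rate = function(L) 1)
  bm <- simulate_benchmark(spec)
  tr <- bm$truth
  expect_true(any(tr$injected))
  b <- run_benchmark(bm)
  long <- b$metrics[b$metrics$length >= 8, ]
  expect_gt(mean(long$delta_sse > 0), 0.5)
})

test_that("the pairing contract holds by construction and output is reproducible", {
  spec <- synthetic_spec(n_proteins = 3, seed = 17,
                         protein_length_range = c(70, 100))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_benchmark_set(spec, d1)
  m2 <- generate_benchmark_set(spec, d2)
  expect_equal(nrow(m1), 3L)
  expect_equal(length(list.files(d1, pattern = "\\.pdb$")), 6L)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readLines(m1$exp_path[i]), readLines(m2$exp_path[i]))
    expect_identical(readLines(m1$pred_path[i]), readLines(m2$pred_path[i]))
    e <- read_structure(m1$exp_path[i], "experimental")
    p <- read_structure(m1$pred_path[i], "predicted")
    expect_identical(residues(e)$aa, residues(p)$aa)   # 100% identity
  }
  tr <- read.delim(file.path(d1, "truth.tsv"))
  expect_true(all(tr$end_idx >= tr$start_idx))
  expect_true(all(tr$sigma >= 0))
})

test_that("synthetic pLDDT sits in range and tracks local accuracy", {
  bm <- small_benchmark(n = 4, seed = 23)
  for (p in bm$pairs) {
    expect_true(all(p$pred$atoms$b >= 0 & p$pred$atoms$b <= 100))
  }
  b <- run_benchmark(bm)
  expect_lt(correlate(b$metrics$mean_plddt, b$metrics$rmsd)$r, 0)
})
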