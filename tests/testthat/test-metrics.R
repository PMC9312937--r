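test_that("kabsch superposition satisfies identity and rigid-invariance", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  sp <- kabsch_superpose(x, x)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
  y <- random_rigid_transform(x)
  expect_equal(kabsch_superpose(x, y)$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(kabsch_superpose(x, y)$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(x, x[1:5, ]), "equal size")
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "3 points")
  # collinear sets are flagged degenerate but still return a minimizer
  line <- cbind(1:5, 0, 0)
  spd <- kabsch_superpose(line, line + 0.1)
  expect_true(spd$degenerate)
  expect_lt(spd$rmsd, 0.2)
})

test_that("kabsch rmsd matches the grid-search oracle on a displaced square", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  moved <- sq
  moved[3, 3] <- 1
  expect_equal(kabsch_superpose(sq, moved)$rmsd, oracle_rmsd(sq, moved),
               tolerance = 1e-3)
})

test_that("rmsd and tm agree with brute-force oracles on random fragments", {
  set.seed(2024)
  for (k in 1:20) {
    n <- sample(4:8, 1)
    base <- matrix(rnorm(3 * n, sd = 3), n, 3)
    noisy <- random_rigid_transform(jitter_coords(base, 0.4, seed = 5000 + k))
    expect_equal(kabsch_superpose(base, noisy)$rmsd,
                 oracle_rmsd(base, noisy), tolerance = 1e-3)
  }
  # TM-score against its own direct-maximization oracle
  set.seed(77)
  for (k in 1:6) {
    n <- sample(c(6, 8, 10), 1)
    bb <- make_ideal_segment("coil", n, seed = 600 + k)
    fixed <- bb$CA
    mobile <- random_rigid_transform(jitter_coords(fixed, 0.5, seed = 700 + k))
    mine <- tm_score(fixed = fixed, mobile = mobile)
    ora <- oracle_tm(fixed, mobile, d0 = tm_d0(n))
    expect_equal(mine, ora, tolerance = 1e-3)
  }
})

test_that("the d0 normalization follows the published length law", {
  expect_equal(tm_d0(65), 1.24 * 50^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_equal(tm_d0(65), 2.768, tolerance = 1e-3)
  # the raw formula is below the 0.5 floor up to L = 21
  expect_equal(tm_d0(21), 0.5)
  expect_lt(1.24 * (21 - 15)^(1 / 3) - 1.8, 0.5)
  expect_equal(tm_d0(22), 1.24 * 7^(1 / 3) - 1.8)
  expect_gt(tm_d0(22), 0.5)
})

test_that("tm is 1 for congruent fragments and never below the naive score", {
  bb <- make_ideal_segment("coil", 9, seed = 12)
  expect_equal(tm_score(fixed = bb$CA, mobile = bb$CA), 1.0, tolerance = 1e-9)
  expect_equal(tm_score(fixed = bb$CA, mobile = random_rigid_transform(bb$CA)),
               1.0, tolerance = 1e-6)
  # search can only improve on a single global Kabsch superposition
  for (k in 1:5) {
    noisy <- jitter_coords(bb$CA, 0.8, seed = 900 + k)
    sp <- kabsch_superpose(bb$CA, noisy)
    naive <- mean(1 / (1 + rowSums((apply_superposition(sp, noisy) - bb$CA)^2) /
                         tm_d0(9)^2))
    expect_gte(tm_score(fixed = bb$CA, mobile = noisy) + 1e-12, naive)
  }
  expect_error(tm_score(fixed = bb$CA[1:2, ], mobile = bb$CA[1:2, ]), "L >= 3")
})

test_that("tm decreases on average as noise grows", {
  bb <- make_ideal_segment("coil", 10, seed = 42)
  mean_tm <- vapply(c(0.1, 0.5, 1.5), function(sig) {
    mean(vapply(1:8, function(k) {
      tm_score(fixed = bb$CA, mobile = jitter_coords(bb$CA, sig, seed = 80 * k))
    }, 1))
  }, 1)
  expect_true(all(diff(mean_tm) < 0))
})

test_that("delta_sse counts regular-class gains as percent of span", {
  expect_equal(delta_sse(NULL, rep("C", 6), c("C", "C", "H", "H", "H", "C")), 50)
  expect_equal(delta_sse(NULL, rep("T", 5), rep("T", 5)), 0)
  expect_equal(delta_sse(NULL, rep("S", 4), rep("H", 4)), 100)
  # identity property for arbitrary class strings
  x <- c("H", "E", "C", "T", "G")
  expect_equal(delta_sse(NULL, x, x), 0)
  expect_error(delta_sse(NULL, rep("C", 3), rep("C", 4)), "span")
})

test_that("mean_plddt is atom-weighted, not residue-weighted", {
  bb <- make_ideal_segment("coil", 2, seed = 8)
  s <- structure_from_backbone(bb, "w2", source = "predicted")
  # residue 1: keep 3 atoms at 60; residue 2: 4 atoms at 90 plus 2 extra
  s$atoms <- s$atoms[-4, ]
  extra <- s$atoms[s$atoms$res_idx == 2, ][1:2, ]
  extra$elety <- c("CB", "CG")
  s$atoms <- rbind(s$atoms, extra)
  s$atoms$b <- ifelse(s$atoms$res_idx == 1, 60, 90)
  loop <- list(res_idx = 1:2, length = 2L)
  expect_equal(mean_plddt(s, loop), (3 * 60 + 6 * 90) / 9)  # 80, not 75
  s2 <- s; s2$source <- "experimental"
  expect_error(mean_plddt(s2, loop), "predicted")
})

test_that("per-loop metrics are exact for identical and rigidly moved predictions", {
  bm <- small_benchmark(n = 2, seed = 61)
  p <- bm$pairs[[1]]
  ea <- assign_secstruct(p$exp)
  loops <- extract_loops(p$exp, ea)
  # a 'prediction' that is the experimental structure itself
  self <- p$exp
  self$source <- "predicted"
  self$id <- "self"
  prs <- pair_loops(p$exp, loops, self, ea)
  for (lp in prs) {
    expect_equal(loop_rmsd(lp, p$exp, self), 0, tolerance = 1e-8)
    expect_equal(tm_score(lp, p$exp, self), 1, tolerance = 1e-8)
    expect_equal(delta_sse(lp, lp$exp$classes, lp$pred$classes), 0)
  }
  # rigid transform leaves rmsd/tm unchanged to 1e-6
  set.seed(3)
  moved <- self
  xyz <- random_rigid_transform(as.matrix(self$atoms[, c("x", "y", "z")]))
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]; moved$atoms$z <- xyz[, 3]
  prs2 <- pair_loops(p$exp, loops, moved, ea)
  for (lp in prs2) {
    expect_equal(loop_rmsd(lp, p$exp, moved), 0, tolerance = 1e-6)
    expect_equal(tm_score(lp, p$exp, moved), 1, tolerance = 1e-6)
  }
})

test_that("rmsd is symmetric and grows with applied noise", {
  bb <- make_ideal_segment("coil", 5, seed = 9)
  a <- do.call(rbind, list(bb$N, bb$CA, bb$C, bb$O))
  b <- jitter_coords(a, 0.3, seed = 4)
  expect_equal(kabsch_superpose(a, b)$rmsd, kabsch_superpose(b, a)$rmsd,
               tolerance = 1e-9)
  rms <- vapply(c(0.1, 0.4, 1.2), function(sig) {
    mean(vapply(1:10, function(k)
      kabsch_superpose(a, jitter_coords(a, sig, seed = 50 * k))$rmsd, 1))
  }, 1)
  expect_true(all(diff(rms) > 0))
})
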