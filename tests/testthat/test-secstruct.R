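test_that("amide hydrogens are placed 1 A from N, skipping prolines and chain starts", {
  bb <- make_ideal_segment("alpha_helix", 6)
  s <- structure_from_backbone(bb, "h6", aa = c("A", "A", "P", "A", "A", "A"))
  sh <- place_amide_hydrogens(s)
  h <- sh$atoms[sh$atoms$elety == "H", ]
  expect_equal(sort(h$res_idx), c(2L, 4L, 5L, 6L))  # no residue 1, no proline
  for (i in h$res_idx) {
    hp <- as.numeric(h[h$res_idx == i, c("x", "y", "z")])
    np <- as.numeric(sh$atoms[sh$atoms$res_idx == i & sh$atoms$elety == "N",
                              c("x", "y", "z")])
    expect_equal(sqrt(sum((hp - np)^2)), 1.0, tolerance = 1e-9)
  }
})

test_that("Kabsch-Sander energies match a direct evaluation of the formula", {
  s <- structure_from_backbone(make_ideal_segment("alpha_helix", 12), "h12")
  sh <- place_amide_hydrogens(s)
  hb <- kabsch_sander_hbonds(sh)
  # the alpha-helical i+4 -> i bonds must be present
  expect_true(all(paste(5:12, 1:8) %in% paste(hb$donor, hb$acceptor)))
  expect_false(any(hb$donor == hb$acceptor))
  expect_false(any(hb$donor == hb$acceptor + 1L))
  # independent energy evaluation for one bond
  pos <- function(i, el) as.numeric(
    sh$atoms[sh$atoms$res_idx == i & sh$atoms$elety == el, c("x", "y", "z")])
  d <- function(p, q) sqrt(sum((p - q)^2))
  e_direct <- 0.084 * 332 *
    (1 / d(pos(1, "O"), pos(5, "N")) + 1 / d(pos(1, "C"), pos(5, "H")) -
     1 / d(pos(1, "O"), pos(5, "H")) - 1 / d(pos(1, "C"), pos(5, "N")))
  expect_lt(e_direct, -0.5)
  expect_equal(hb$energy[hb$donor == 5 & hb$acceptor == 1], e_direct,
               tolerance = 1e-9)
  # residues far apart contribute nothing
  far <- structure_from_backbone(list(
    N = rbind(c(0, 0, 0), c(30, 0, 0)), CA = rbind(c(1.5, 0, 0), c(31.5, 0, 0)),
    C = rbind(c(2, 1.4, 0), c(32, 1.4, 0)), O = rbind(c(1.3, 2.4, 0), c(31.3, 2.4, 0))),
    "far2")
  expect_equal(nrow(kabsch_sander_hbonds(far)), 0L)
})

test_that("ideal folds are assigned their canonical classes", {
  h <- assign_secstruct(structure_from_backbone(
    make_ideal_segment("alpha_helix", 12), "h12"))
  expect_true(all(h$class8[3:10] == "H"))
  expect_false(h$class8[1] == "H")
  expect_false(h$class8[12] == "H")
  hp <- assign_secstruct(build_beta_hairpin(5))
  expect_true(all(hp$class8[c(2:5, 8:11)] == "E"))
  ext <- assign_secstruct(structure_from_backbone(
    build_backbone(rep(180, 10), rep(180, 10)), "ext"))
  expect_false(any(ext$class8 %in% c("H", "G", "I", "E")))
  # chains shorter than 3 residues carry no structure
  tiny <- assign_secstruct(structure_from_backbone(
    make_ideal_segment("coil", 2, seed = 1), "tiny"))
  expect_true(all(tiny$class8 == "C"))
})

test_that("assignment agrees with the reference DSSP program on stored fixtures", {
  loopset <- c("C", "T", "S")
  for (id in c("helix12", "strand10", "beta_hairpin", "extended10", "coil8",
               "synthprot1", "synthprot2")) {
    s <- read_structure(fixture_path(paste0(id, ".pdb")), "experimental")
    mine <- assign_secstruct(s)$class8
    ref <- strsplit(readLines(fixture_path(paste0(id, ".dssp.txt")))[1], "")[[1]]
    expect_equal(length(mine), length(ref))
    agreement <- mean((mine %in% loopset) == (ref %in% loopset))
    expect_gte(agreement, 0.95)
  }
})

test_that("assignment is invariant under rigid-body motion", {
  s <- read_structure(fixture_path("synthprot1.pdb"), "experimental")
  before <- assign_secstruct(s)$class8
  set.seed(99)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  moved <- random_rigid_transform(xyz)
  s$atoms$x <- moved[, 1]; s$atoms$y <- moved[, 2]; s$atoms$z <- moved[, 3]
  expect_identical(assign_secstruct(s)$class8, before)
})

test_that("loop mask is exactly the none/turn/bend collapse", {
  s <- read_structure(fixture_path("synthprot1.pdb"), "experimental")
  a <- assign_secstruct(s)
  expect_identical(loop_mask(a), a$class8 %in% c("C", "T", "S"))
  expect_equal(length(loop_mask(a)), nrow(residues(s)))
  expect_true(all(a$kappa >= 0 & a$kappa <= 180, na.rm = TRUE))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_secstruct_tsv(a, p)
  tab <- read.delim(p)
  expect_equal(nrow(tab), nrow(a))
})
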