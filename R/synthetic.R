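# Deterministic generator of paired (experimental, predicted) structures.
#
# Synthetic proteins alternate alpha-helical scaffold segments with coil
# loops whose lengths follow a geometric law calibrated so that ~83% of
# loops (of length >= 3) are shorter than 10 residues and ~98% shorter than
# 20, and whose overall loop-residue fraction is drawn around 40%. The
# "predicted" copy adds per-loop isotropic coordinate noise growing with
# loop length, occasionally rebuilds a loop sub-span with helical torsions
# (the spurious-helix error mode), and writes a synthetic pLDDT confidence,
# anticorrelated with the local displacement, into the B-factor column.

#' Specification of a synthetic benchmark set
#'
#' Defaults define the emulated study conditions; see the methods vignette
#' for the calibration rationale.
#'
#' @param n_proteins number of protein pairs.
#' @param seed master seed; identical specs reproduce identical sets.
#' @param loop_geom_p geometric-decay parameter of loop length `3 + rgeom(p)`
#'   (0.2217 puts ~83% of loops below 10 residues and ~98.6% below 20).
#' @param short_loop_prob probability of a 1-2 residue loop (filtered out of
#'   the benchmark by the minimum-length rule but present in the chains).
#' @param target_loop_fraction,loop_fraction_sd per-protein loop-residue
#'   fraction is drawn from this normal law (clamped to \[0.2, 0.95\]).
#' @param protein_length_range inclusive range of chain lengths.
#' @param noise_sigma function of loop length L returning the per-atom
#'   Gaussian noise sd in Angstrom (default `0.047 * L^1.19`, anchored to
#'   stratified mean RMSDs of ~0.33 A below 10 residues and ~2 A above 20).
#' @param sse_noise noise sd applied to non-loop residues, Angstrom.
#' @param helix_injection_rate function of L returning the probability that
#'   a loop of the predicted copy gains a helical sub-span (default
#'   `min(0.95, max(0, 0.018 * (L - 5)))`; loops shorter than 6 are never
#'   eligible).
#' @param plddt_base,plddt_span,plddt_decay,plddt_jitter synthetic
#'   confidence model `clamp(base + span * exp(-disp / decay) + N(0, jitter),
#'   0, 100)` where `disp` is the mean per-residue displacement in Angstrom.
#' @param sequence_mode `"polyA"` (default) or `"random"` (uniform over the
#'   19 non-proline residues; needed by hydropathy analyses).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 25L, seed = 1L,
                           loop_geom_p = 0.2217, short_loop_prob = 0.08,
                           target_loop_fraction = 0.40,
                           loop_fraction_sd = 0.06,
                           protein_length_range = c(120L, 280L),
                           noise_sigma = function(L) 0.047 * L^1.19,
                           sse_noise = 0.05,
                           helix_injection_rate = function(L)
                             pmin(0.95, pmax(0, 0.018 * (L - 5))),
                           plddt_base = 55, plddt_span = 40,
                           plddt_decay = 1.0, plddt_jitter = 2.5,
                           sequence_mode = c("polyA", "random")) {
  stopifnot(n_proteins >= 1L, loop_geom_p > 0, loop_geom_p < 1,
            short_loop_prob >= 0, short_loop_prob <= 1,
            target_loop_fraction > 0, target_loop_fraction <= 1,
            sse_noise >= 0)
  structure(list(
    n_proteins = as.integer(n_proteins), seed = as.integer(seed),
    loop_geom_p = loop_geom_p, short_loop_prob = short_loop_prob,
    target_loop_fraction = target_loop_fraction,
    loop_fraction_sd = loop_fraction_sd,
    protein_length_range = protein_length_range,
    noise_sigma = noise_sigma, sse_noise = sse_noise,
    helix_injection_rate = helix_injection_rate,
    plddt_base = plddt_base, plddt_span = plddt_span,
    plddt_decay = plddt_decay, plddt_jitter = plddt_jitter,
    sequence_mode = match.arg(sequence_mode)
  ), class = "synthetic_spec")
}

# Coil torsions drawn from non-helical, non-strand basins (PPII, extended,
# bridge, near-polyproline); verified to yield 0% regular SS on isolated
# chains under the eight-class assignment.
sample_coil_torsions <- function(n) {
  basins <- matrix(c(-70, 145, -140, 160, -85, -5, -75, 100),
                   ncol = 2L, byrow = TRUE)
  k <- sample.int(4L, n, replace = TRUE, prob = c(0.35, 0.3, 0.15, 0.2))
  cbind(basins[k, 1L] + stats::runif(n, -15, 15),
        basins[k, 2L] + stats::runif(n, -15, 15))
}

#' Ideal backbone segment
#'
#' Builds an isolated backbone with canonical torsions: alpha helix
#' (phi = -57, psi = -47), beta strand (phi = -119, psi = +113), or coil
#' torsions sampled from broad non-helical, non-strand basins.
#'
#' @param kind `"alpha_helix"`, `"beta_strand"` or `"coil"`.
#' @param length number of residues (>= 1).
#' @param seed RNG seed (used by `"coil"` only).
#' @return list of N/CA/C/O coordinate matrices (see [build_backbone()]).
#' @export
make_ideal_segment <- function(kind = c("alpha_helix", "beta_strand", "coil"),
                               length, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(length >= 1L)
  tor <- switch(kind,
    alpha_helix = cbind(rep(-57, length), rep(-47, length)),
    beta_strand = cbind(rep(-119, length), rep(113, length)),
    coil = {
      old <- .save_rng(); on.exit(.restore_rng(old))
      set.seed(seed)
      sample_coil_torsions(length)
    })
  build_backbone(tor[, 1L], tor[, 2L])
}

#' Antiparallel beta-hairpin fixture
#'
#' Two strands joined by a type II' turn; under the eight-class assignment
#' the strand interiors are E.
#'
#' @param strand_len residues per strand (>= 3).
#' @return an experimental-source [protein_structure()].
#' @export
build_beta_hairpin <- function(strand_len = 5L) {
  stopifnot(strand_len >= 3L)
  phi <- c(rep(-119, strand_len), 60, -80, rep(-119, strand_len))
  psi <- c(rep(113, strand_len), -120, 0, rep(113, strand_len))
  structure_from_backbone(build_backbone(phi, psi), id = "beta_hairpin")
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

.draw_loop_len <- function(spec) {
  if (stats::runif(1) < spec$short_loop_prob) sample(1:2, 1L)
  else 3L + stats::rgeom(1L, spec$loop_geom_p)
}

#' Build one synthetic experimental protein
#'
#' Alternating coil/helix architecture; the realised loop fraction is drawn
#' around the spec's target and loop lengths follow its geometric law. With
#' `target_loop_fraction = 1` the protein is all coil.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed for this protein.
#' @param id structure id.
#' @return list: `structure` (experimental [protein_structure()]) and
#'   `design` (data.frame of designed segments: `kind`, `start`, `end`).
#' @export
build_protein <- function(spec, seed = spec$seed, id = "synthetic") {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n_target <- sample(spec$protein_length_range[1L]:spec$protein_length_range[2L], 1L)
  f <- min(0.95, max(0.2, stats::rnorm(1, spec$target_loop_fraction,
                                       spec$loop_fraction_sd)))
  all_coil <- spec$target_loop_fraction >= 0.999
  mean_loop <- 3 + (1 - spec$loop_geom_p) / spec$loop_geom_p
  mean_helix <- mean_loop * (1 - f) / f
  kinds <- character(0); lens <- integer(0)
  total <- 0L; want_loop <- TRUE
  while (total < n_target) {
    if (want_loop || all_coil) {
      k <- "L"; l <- .draw_loop_len(spec)
    } else {
      k <- "H"; l <- max(6L, round(stats::rnorm(1, mean_helix, 2)))
    }
    kinds <- c(kinds, k); lens <- c(lens, l); total <- total + l
    want_loop <- !want_loop
  }
  if (kinds[length(kinds)] == "H") { kinds <- c(kinds, "L"); lens <- c(lens, .draw_loop_len(spec)) }
  phi <- numeric(0); psi <- numeric(0)
  for (i in seq_along(kinds)) {
    l <- lens[i]
    if (kinds[i] == "H") {
      phi <- c(phi, -57 + stats::runif(l, -3, 3))
      psi <- c(psi, -47 + stats::runif(l, -3, 3))
    } else {
      t <- sample_coil_torsions(l)
      phi <- c(phi, t[, 1L]); psi <- c(psi, t[, 2L])
    }
  }
  n <- length(phi)
  aa <- if (spec$sequence_mode == "random") {
    sample(setdiff(names(.kyte_doolittle), "P"), n, replace = TRUE)
  } else rep("A", n)
  bfac <- pmin(80, pmax(2, stats::rnorm(n, 25, 8)))
  s <- structure_from_backbone(build_backbone(phi, psi), id = id,
                               source = "experimental", aa = aa, bfac = bfac)
  ends <- cumsum(lens)
  design <- data.frame(kind = kinds, start = c(1L, utils::head(ends, -1L) + 1L),
                       end = ends, stringsAsFactors = FALSE)
  list(structure = s, design = design)
}

#' Perturb an experimental structure into a synthetic prediction
#'
#' Loop spans are fixed on the clean experimental structure (its own
#' secondary-structure assignment), then: every loop receives isotropic
#' Gaussian coordinate noise of sd `noise_sigma(L)`; with probability
#' `helix_injection_rate(L)` a sub-span of >= 6 residues is rebuilt with
#' helical torsions (anchored at the preceding residue, so the chain stays
#' continuous upstream); non-loop residues receive `sse_noise`; and all
#' B-factors are overwritten with the synthetic pLDDT model. The sequence is
#' unchanged, so every pair is 100% identical by construction.
#'
#' @param s experimental [protein_structure()].
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed.
#' @return list: `structure` (predicted [protein_structure()]) and `truth`
#'   (data.frame per loop: `chain`, `start_idx`, `end_idx`, `length`,
#'   `sigma`, `injected`, `inj_start`, `inj_len`).
#' @export
perturb_to_prediction <- function(s, spec, seed = spec$seed) {
  if (s$source != "experimental") stop("expects an experimental structure")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  a <- assign_secstruct(s)
  loops <- extract_loops(s, a, min_len = 1L)
  rt <- residues(s)
  n <- nrow(rt)
  atoms <- s$atoms
  disp_target <- numeric(n)            # per-residue noise sd
  disp_target[] <- spec$sse_noise
  truth <- list()
  helix_spans <- list()
  for (lp in loops) {
    L <- lp$length
    sigma <- spec$noise_sigma(L)
    disp_target[lp$res_idx] <- sigma
    inj <- FALSE; inj_start <- NA_integer_; inj_len <- NA_integer_
    if (L >= 6L && lp$res_idx[1L] >= 2L &&
        stats::runif(1) < spec$helix_injection_rate(L)) {
      inj_len <- sample(6L:min(L, 10L), 1L)
      inj_start <- lp$res_idx[1L] + sample(0:(L - inj_len), 1L)
      if (inj_start < 2L) inj_start <- 2L
      inj <- TRUE
      helix_spans[[length(helix_spans) + 1L]] <- c(inj_start, inj_len)
      disp_target[inj_start:(inj_start + inj_len - 1L)] <- spec$sse_noise
    }
    truth[[length(truth) + 1L]] <- data.frame(
      chain = lp$chain, start_idx = lp$res_idx[1L],
      end_idx = lp$res_idx[L], length = L, sigma = sigma, injected = inj,
      inj_start = inj_start, inj_len = inj_len, stringsAsFactors = FALSE)
  }
  # helical rebuilds first (anchored on the clean coordinates)
  for (hs in helix_spans) {
    st <- hs[1L]; len <- hs[2L]
    anchor <- st - 1L
    seg <- build_backbone(rep(-57, len + 1L), rep(-47, len + 1L))
    seg_anchor <- rbind(seg$N[1L, ], seg$CA[1L, ], seg$C[1L, ], seg$O[1L, ])
    tgt <- rbind(
      as.numeric(atoms[atoms$res_idx == anchor & atoms$elety == "N", c("x", "y", "z")]),
      as.numeric(atoms[atoms$res_idx == anchor & atoms$elety == "CA", c("x", "y", "z")]),
      as.numeric(atoms[atoms$res_idx == anchor & atoms$elety == "C", c("x", "y", "z")]),
      as.numeric(atoms[atoms$res_idx == anchor & atoms$elety == "O", c("x", "y", "z")]))
    if (anyNA(tgt)) next
    sp <- kabsch_superpose(tgt, seg_anchor)
    for (k in seq_len(len)) {
      ri <- st + k - 1L
      new <- apply_superposition(sp, rbind(seg$N[k + 1L, ], seg$CA[k + 1L, ],
                                           seg$C[k + 1L, ], seg$O[k + 1L, ]))
      for (m in seq_along(c("N", "CA", "C", "O"))) {
        el <- c("N", "CA", "C", "O")[m]
        row <- which(atoms$res_idx == ri & atoms$elety == el)
        if (length(row)) atoms[row, c("x", "y", "z")] <- new[m, , drop = FALSE]
      }
    }
  }
  # coordinate noise; disp_target is the RMS displacement magnitude, so each
  # coordinate gets sd sigma / sqrt(3)
  sd_per_atom <- disp_target[atoms$res_idx] / sqrt(3)
  na <- nrow(atoms)
  atoms$x <- atoms$x + stats::rnorm(na, 0, sd_per_atom)
  atoms$y <- atoms$y + stats::rnorm(na, 0, sd_per_atom)
  atoms$z <- atoms$z + stats::rnorm(na, 0, sd_per_atom)
  # synthetic pLDDT from realised per-residue displacement
  disp <- sqrt((atoms$x - s$atoms$x)^2 + (atoms$y - s$atoms$y)^2 +
                 (atoms$z - s$atoms$z)^2)
  disp_res <- tapply(disp, atoms$res_idx, mean)
  plddt <- pmin(100, pmax(0, spec$plddt_base +
    spec$plddt_span * exp(-as.numeric(disp_res) / spec$plddt_decay) +
    stats::rnorm(length(disp_res), 0, spec$plddt_jitter)))
  atoms$b <- round(plddt[match(atoms$res_idx, as.numeric(names(disp_res)))], 2L)
  pred <- protein_structure(id = paste0(s$id, "_pred"), source = "predicted",
                            atoms = atoms)
  list(structure = pred,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Simulate a full benchmark set in memory
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_benchmark`: `pairs` (each with `exp`,
#'   `pred`) and `truth` (row-bound truth records with a `protein` column).
#' @export
simulate_benchmark <- function(spec) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * spec$n_proteins)
  pairs <- vector("list", spec$n_proteins)
  truth <- list()
  for (i in seq_len(spec$n_proteins)) {
    id <- sprintf("synth%03d", i)
    bp <- build_protein(spec, seed = sub_seeds[2L * i - 1L], id = id)
    pp <- perturb_to_prediction(bp$structure, spec, seed = sub_seeds[2L * i])
    pairs[[i]] <- list(exp = bp$structure, pred = pp$structure)
    if (!is.null(pp$truth)) {
      pp$truth$protein <- id
      truth[[length(truth) + 1L]] <- pp$truth
    }
  }
  structure(list(pairs = pairs,
                 truth = do.call(rbind, truth), spec = spec),
            class = "synthetic_benchmark")
}

#' Replicate experimental structures for ensemble analyses
#'
#' Independent experimental determinations of one protein are emulated by
#' adding small uniform coordinate noise to a reference structure.
#'
#' @param s reference experimental [protein_structure()].
#' @param n_rep number of replicates.
#' @param sigma per-atom RMS displacement in Angstrom (default 0.33, giving
#'   pairwise replicate loop RMSDs around 0.35 A).
#' @param seed RNG seed.
#' @return list of experimental [protein_structure()]s (reference excluded).
#' @export
make_ensemble_replicates <- function(s, n_rep = 2L, sigma = 0.33, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sdc <- sigma / sqrt(3)
  lapply(seq_len(n_rep), function(k) {
    r <- s
    na <- nrow(r$atoms)
    r$atoms$x <- r$atoms$x + stats::rnorm(na, 0, sdc)
    r$atoms$y <- r$atoms$y + stats::rnorm(na, 0, sdc)
    r$atoms$z <- r$atoms$z + stats::rnorm(na, 0, sdc)
    r$id <- paste0(s$id, "_rep", k)
    r
  })
}

#' Write a benchmark set to disk
#'
#' Emits `<id>_exp.pdb` / `<id>_pred.pdb` pairs, a `truth.tsv` table, a
#' `manifest.tsv` (exp_path, pred_path) and a `spec.txt` record. Re-running
#' with the same spec reproduces identical files.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
generate_benchmark_set <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bm <- simulate_benchmark(spec)
  manifest <- data.frame(exp_path = character(0), pred_path = character(0))
  for (p in bm$pairs) {
    fe <- file.path(out_dir, paste0(p$exp$id, "_exp.pdb"))
    fp <- file.path(out_dir, paste0(p$exp$id, "_pred.pdb"))
    write_structure(p$exp, fe)
    write_structure(p$pred, fp)
    manifest <- rbind(manifest, data.frame(exp_path = fe, pred_path = fp))
  }
  utils::write.table(bm$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fixed <- bm$spec[!vapply(bm$spec, is.function, TRUE)]
  writeLines(paste(names(fixed),
                   vapply(fixed, function(v) paste(v, collapse = " "), ""),
                   sep = " = "),
             file.path(out_dir, "spec.txt"))
  invisible(manifest)
}
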