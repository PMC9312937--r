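# Per-loop similarity and confidence metrics: least-squares (Kabsch)
# superposition and RMSD, TM-score with the d0 length normalization and an
# iterative fragment-seeded search, change in regular secondary-structure
# content, and atom-averaged pLDDT.

#' Optimal rigid superposition of two point sets (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD of `mobile`
#' onto `fixed`, via SVD of the cross-covariance matrix with reflection
#' correction.
#'
#' @param fixed,mobile N x 3 coordinate matrices with matching rows, N >= 3.
#' @return list of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length-3), `rmsd`, `degenerate` (TRUE for collinear or
#'   rank-deficient point sets). The transform maps a mobile point x to
#'   `rotation %*% (x - centroid_mobile) + centroid_fixed + translation0`,
#'   i.e. apply with [apply_superposition()].
#' @export
kabsch_superpose <- function(fixed, mobile) {
  fixed <- as.matrix(fixed); mobile <- as.matrix(mobile)
  if (!all(dim(fixed) == dim(mobile)) || ncol(fixed) != 3L) {
    stop("fixed and mobile must be N x 3 matrices of equal size")
  }
  if (nrow(fixed) < 3L) stop("superposition needs at least 3 points")
  if (!all(is.finite(fixed)) || !all(is.finite(mobile))) {
    stop("coordinates must be finite")
  }
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  F <- sweep(fixed, 2L, cf); M <- sweep(mobile, 2L, cm)
  H <- crossprod(M, F)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Mt <- M %*% t(R)
  rmsd <- sqrt(mean(rowSums((Mt - F)^2)))
  degenerate <- sv$d[3L] < 1e-8 * max(sv$d[1L], 1e-12)
  structure(list(rotation = R, translation = cf, centroid_mobile = cm,
                 rmsd = rmsd, degenerate = degenerate),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sp a `superposition` from [kabsch_superpose()].
#' @param x N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(sp, x) {
  sweep(sweep(as.matrix(x), 2L, sp$centroid_mobile) %*% t(sp$rotation),
        2L, sp$translation, `+`)
}

#' Per-loop RMSD after local superposition
#'
#' Superposes the two fragments of a loop pair on themselves (local frame)
#' and returns the RMSD over the selected atom set. If any residue is
#' incomplete for the requested set, the computation falls back to CA atoms
#' with a message.
#'
#' @param p a `loop_pair`.
#' @param exp_s,pred_s the parent structures.
#' @param atom_set `"backbone"` (N, CA, C, O; default), `"CA"` or `"heavy"`.
#' @return RMSD in Angstrom.
#' @export
loop_rmsd <- function(p, exp_s, pred_s, atom_set = "backbone") {
  fx <- loop_coordinates(exp_s, p$exp, atom_set)
  mb <- loop_coordinates(pred_s, p$pred, atom_set)
  if (is.null(fx) || is.null(mb) || nrow(fx) != nrow(mb)) {
    message("incomplete ", atom_set, " atoms for ", p$pair_id,
            "; falling back to CA")
    fx <- loop_coordinates(exp_s, p$exp, "CA")
    mb <- loop_coordinates(pred_s, p$pred, "CA")
  }
  kabsch_superpose(fx, mb)$rmsd
}

#' TM-score distance scale d0
#'
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8`, floored at `d0_min` (0.5 Angstrom by
#' default); the raw formula is non-positive for short fragments (L <= 21).
#'
#' @param L normalization length in residues.
#' @param d0_min floor in Angstrom.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L, d0_min = 0.5) {
  x <- L - 15
  raw <- 1.24 * sign(x) * abs(x)^(1 / 3) - 1.8
  pmax(d0_min, raw)
}

# The 24 proper rotations of the cube (cached), used as global search seeds.
.cube_rot_cache <- new.env(parent = emptyenv())
.cube_rotations <- function() {
  if (!is.null(.cube_rot_cache$R)) return(.cube_rot_cache$R)
  spec <- c(
    lapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), function(ax)
      lapply(c(pi / 2, pi, 3 * pi / 2), function(th) list(ax, th))),
    lapply(list(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                c(0, 1, 1), c(0, 1, -1)), function(ax)
      list(list(ax, pi))),
    lapply(list(c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1)),
           function(ax)
      lapply(c(2 * pi / 3, 4 * pi / 3), function(th) list(ax, th))))
  out <- c(list(diag(3)), lapply(unlist(spec, recursive = FALSE),
                                 function(s) {
    u <- s[[1]] / sqrt(sum(s[[1]]^2))
    .rotvec_to_matrix(u * s[[2]])
  }))
  .cube_rot_cache$R <- out
  out
}

# Rotation from a length-3 rotation-vector (axis * angle, radians).
.rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.tm_eval <- function(fixed, moved, d0) {
  d2 <- rowSums((moved - fixed)^2)
  mean(1 / (1 + d2 / d0^2))
}

#' TM-score of a loop pair
#'
#' Template-modeling score `(1/L) * sum_i 1 / (1 + (d_i/d0)^2)` with the
#' residue correspondence fixed by 100% sequence identity, maximized over
#' rigid superpositions. Seeds come from Kabsch superpositions of all
#' contiguous CA fragments of lengths L, L/2 and L/4 (minimum 4); each seed
#' is refined by iteratively re-superposing on the residues currently within
#' a d0-dependent distance cutoff until the subset is stable, and the best
#' candidate receives a final direct maximization of the score over the
#' rigid-motion parameters. Normalization length L is the loop length.
#'
#' @param p a `loop_pair` (or NULL when `fixed`/`mobile` are given).
#' @param exp_s,pred_s parent structures.
#' @param d0_min floor for d0 (default 0.5 Angstrom).
#' @param fixed,mobile optional explicit L x 3 CA matrices, bypassing the
#'   structures.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(p = NULL, exp_s = NULL, pred_s = NULL, d0_min = 0.5,
                     fixed = NULL, mobile = NULL) {
  if (is.null(fixed)) {
    fixed <- loop_coordinates(exp_s, p$exp, "CA")
    mobile <- loop_coordinates(pred_s, p$pred, "CA")
  }
  fixed <- as.matrix(fixed); mobile <- as.matrix(mobile)
  L <- nrow(fixed)
  if (L < 3L || nrow(mobile) != L) stop("TM-score needs matched L >= 3 fragments")
  d0 <- tm_d0(L, d0_min)
  d_cut <- max(d0 + 1.5, 3.5)
  score_of <- function(sp) .tm_eval(fixed, apply_superposition(sp, mobile), d0)
  cm <- colMeans(mobile)
  # direct score maximization around a seed superposition (rotation-vector
  # perturbation + translation), used to polish every seed
  polish <- function(sp, maxit = 200, reltol = 1e-8) {
    M0 <- sweep(mobile, 2L, sp$centroid_mobile) %*% t(sp$rotation)
    obj <- function(par) {
      Rd <- .rotvec_to_matrix(par[1:3])
      moved <- sweep(M0 %*% t(Rd), 2L, sp$translation + par[4:6], `+`)
      -.tm_eval(fixed, moved, d0)
    }
    op <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = reltol))
    list(score = -op$value,
         sp = list(rotation = .rotvec_to_matrix(op$par[1:3]) %*% sp$rotation,
                   translation = sp$translation + op$par[4:6],
                   centroid_mobile = sp$centroid_mobile))
  }
  # polished global superposition first: when the whole fragment already
  # matches closely (score >= 0.9) the landscape is unimodal and the
  # multistart search below cannot add more than ~5e-4 -- return directly
  sp_all <- kabsch_superpose(fixed, mobile)
  nat <- polish(polish(sp_all, maxit = 400)$sp, maxit = 800, reltol = 1e-12)
  if (nat$score >= 0.9) return(nat$score)
  seeds <- list(sp_all)
  win_lens <- unique(pmin(L, pmax(min(4L, L),
                                  c(L, ceiling(L / 2), ceiling(L / 4)))))
  for (wl in win_lens) {
    for (st in seq_len(L - wl + 1L)) {
      idx <- st:(st + wl - 1L)
      sp <- kabsch_superpose(fixed[idx, , drop = FALSE],
                             mobile[idx, , drop = FALSE])
      # iterative subset refinement
      prev <- integer(0)
      for (it in 1:20) {
        moved <- apply_superposition(sp, mobile)
        sub <- which(sqrt(rowSums((moved - fixed)^2)) < d_cut)
        if (length(sub) < 3L) break
        if (identical(sub, prev)) break
        prev <- sub
        sp <- kabsch_superpose(fixed[sub, , drop = FALSE],
                               mobile[sub, , drop = FALSE])
      }
      seeds[[length(seeds) + 1L]] <- sp
    }
  }
  # closest-subset iterations from the global superposition recover poses
  # that align small non-contiguous subsets tightly
  for (m in unique(pmin(L - 1L, c(3L, 4L, 5L, 6L, ceiling(L / 2))))) {
    if (m < 3L) next
    sp <- sp_all
    prev <- integer(0)
    for (it in 1:30) {
      d <- sqrt(rowSums((apply_superposition(sp, mobile) - fixed)^2))
      sub <- sort(order(d)[seq_len(m)])
      if (identical(sub, prev)) break
      prev <- sub
      sp <- kabsch_superpose(fixed[sub, , drop = FALSE],
                             mobile[sub, , drop = FALSE])
    }
    seeds[[length(seeds) + 1L]] <- sp
  }
  # centroid-aligned seeds over the 24-element rotation group of the cube
  # widen basin coverage beyond fragment-seeded superpositions; only the
  # most promising rotations (by raw score) are carried into the polish
  cf <- colMeans(fixed)
  rot_seeds <- lapply(.cube_rotations(), function(R)
    list(rotation = R, translation = cf, centroid_mobile = cm))
  rot_sc <- vapply(rot_seeds, score_of, 1)
  seeds <- c(seeds, rot_seeds[utils::head(order(rot_sc, decreasing = TRUE), 8L)])
  # two-stage basin search: medium polish of every seed, deep polish of the
  # best few, then a tight final polish of the winner
  shallow <- lapply(seeds, polish, maxit = 150)
  sc <- vapply(shallow, `[[`, 1, "score")
  best <- nat$score; best_sp <- nat$sp
  for (k in utils::head(order(sc, decreasing = TRUE), 8L)) {
    pol <- polish(shallow[[k]]$sp, maxit = 500)
    if (pol$score > best) { best <- pol$score; best_sp <- pol$sp }
  }
  max(best, polish(best_sp, maxit = 800, reltol = 1e-12)$score)
}

#' Change in regular secondary-structure content of a loop
#'
#' `100 * (n_regular(pred) - n_regular(exp)) / length`, where regular means
#' class in `{H, G, I, E, B}`. Classes must be the full-structure assignment
#' restricted to the loop span on each side; for dataset-conforming loops the
#' experimental term is 0 by construction.
#'
#' @param p a `loop_pair` (used for the span length check; may be NULL).
#' @param exp_classes,pred_classes character vectors of eight-class codes
#'   over the span.
#' @return percent change, positive when the prediction gains structure.
#' @export
delta_sse <- function(p = NULL, exp_classes, pred_classes) {
  if (length(exp_classes) != length(pred_classes)) {
    stop("class vectors must cover the same span")
  }
  if (!is.null(p) && length(exp_classes) != p$exp$length) {
    stop("class vectors do not match the loop span")
  }
  reg <- c("H", "G", "I", "E", "B")
  100 * (sum(pred_classes %in% reg) - sum(exp_classes %in% reg)) /
    length(exp_classes)
}

#' Atom-averaged pLDDT of a predicted loop fragment
#'
#' Arithmetic mean of the per-atom pLDDT (B-factor column) over all atoms of
#' the fragment — atom-weighted, not residue-weighted.
#'
#' @param s predicted-source [protein_structure()].
#' @param loop a `loop_region` of `s`.
#' @return mean pLDDT in \[0, 100\].
#' @export
mean_plddt <- function(s, loop) {
  if (s$source != "predicted") stop("mean_plddt expects a predicted structure")
  b <- s$atoms$b[s$atoms$res_idx %in% loop$res_idx]
  if (!length(b)) stop("loop fragment has no atoms")
  mean(b)
}

#' All per-loop metrics for one pair
#'
#' @param p a `loop_pair` whose predicted side carries classes (see
#'   [pair_loops()]).
#' @param exp_s,pred_s parent structures.
#' @param atom_set RMSD atom set (default `"backbone"`).
#' @param d0_min TM-score d0 floor.
#' @return one-row data.frame: `pair_id`, `length`, `rmsd`, `tm`,
#'   `delta_sse`, `mean_plddt`.
#' @export
loop_metrics <- function(p, exp_s, pred_s, atom_set = "backbone",
                         d0_min = 0.5) {
  data.frame(
    pair_id = p$pair_id,
    length = p$exp$length,
    rmsd = loop_rmsd(p, exp_s, pred_s, atom_set),
    tm = tm_score(p, exp_s, pred_s, d0_min),
    delta_sse = delta_sse(p, p$exp$classes, p$pred$classes),
    mean_plddt = mean_plddt(pred_s, p$pred),
    stringsAsFactors = FALSE
  )
}
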