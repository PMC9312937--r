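# From-scratch DSSP-style secondary-structure assignment.
#
# The assignment follows the classic Kabsch-Sander scheme: backbone amide
# hydrogens are placed geometrically, hydrogen bonds are scored with the
# four-distance electrostatic energy and accepted below -0.5 kcal/mol,
# n-turn / bridge / ladder patterns yield the eight classes
# H (alpha helix), G (3-10 helix), I (pi helix), E (sheet), B (isolated
# bridge), T (turn), S (bend, Calpha curvature > 70 degrees) and C (none).
# Residues classified C, T or S constitute the loop definition used by the
# whole benchmark.

.KS_QQF <- 0.084 * 332          # q1*q2*f, kcal*Angstrom/mol
.KS_CUTOFF <- -0.5              # H-bond acceptance energy, kcal/mol
.KS_MIN_DIST <- 0.5             # clash guard on any of the four distances
.CA_BREAK <- 4.5                # chain-break threshold on CA-CA, Angstrom
.BEND_KAPPA <- 70               # bend threshold, degrees

#' Place backbone amide hydrogens
#'
#' Standard DSSP convention: for every residue after the first of a segment,
#' H sits 1.0 Angstrom from N along the direction of the previous residue's
#' O -> C vector. Prolines and segment-start residues get no H. Residues with
#' missing backbone atoms are skipped.
#'
#' @param s a [protein_structure()] whose residues carry N, C and O atoms.
#' @return the structure with `H` atoms appended to the atom table.
#' @export
place_amide_hydrogens <- function(s) {
  rt <- residues(s)
  N <- atom_coords(s, "N", rt); C <- atom_coords(s, "C", rt)
  O <- atom_coords(s, "O", rt); CA <- atom_coords(s, "CA", rt)
  seg <- .segment_ids(rt, CA)
  n <- nrow(rt)
  keep <- s$atoms[s$atoms$elety != "H", , drop = FALSE]
  hrows <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == 1L || seg[i] != seg[i - 1L]) next
    if (rt$aa[i] == "P") next
    if (anyNA(N[i, ]) || anyNA(C[i - 1L, ]) || anyNA(O[i - 1L, ])) next
    h <- N[i, ] + unitv(C[i - 1L, ] - O[i - 1L, ])
    tmpl <- keep[match(rt$res_idx[i], keep$res_idx), , drop = FALSE]
    tmpl$elety <- "H"
    tmpl$x <- h[1L]; tmpl$y <- h[2L]; tmpl$z <- h[3L]
    hrows[[i]] <- tmpl
  }
  out <- rbind(keep, do.call(rbind, hrows))
  out <- out[order(out$res_idx), , drop = FALSE]
  rownames(out) <- NULL
  s$atoms <- out
  s
}

# Segment ids: consecutive residues belong to the same segment unless the
# chain id changes, either residue is backbone-incomplete, or the CA-CA
# distance exceeds the break threshold. Patterns never cross segments.
.segment_ids <- function(rt, CA) {
  n <- nrow(rt)
  if (n == 0L) return(integer(0))
  brk <- logical(n)
  if (n > 1L) {
    for (i in 2:n) {
      gap <- if (anyNA(CA[i, ]) || anyNA(CA[i - 1L, ])) Inf else
        vnorm(CA[i, ] - CA[i - 1L, ])
      brk[i] <- rt$chain[i] != rt$chain[i - 1L] || !rt$complete[i] ||
        !rt$complete[i - 1L] || gap > .CA_BREAK
    }
  }
  cumsum(brk) + 1L
}

#' Kabsch-Sander backbone hydrogen bonds
#'
#' Scores every candidate donor (N-H) / acceptor (C=O) pair within 9 Angstrom
#' CA-CA with the electrostatic energy
#' `E = 0.084 * 332 * (1/r(ON) + 1/r(CH) - 1/r(OH) - 1/r(CN))` kcal/mol and
#' keeps, per donor, the two lowest-energy bonds below -0.5 kcal/mol. The
#' donor directly following the acceptor in the chain is excluded (its H and
#' the acceptor O share a peptide plane).
#'
#' @param s a [protein_structure()]; hydrogens are placed if absent.
#' @return data.frame with columns `donor`, `acceptor` (global residue
#'   indices) and `energy` (kcal/mol).
#' @export
kabsch_sander_hbonds <- function(s) {
  if (!any(s$atoms$elety == "H")) s <- place_amide_hydrogens(s)
  rt <- residues(s)
  n <- nrow(rt)
  CA <- atom_coords(s, "CA", rt)
  N <- atom_coords(s, "N", rt); C <- atom_coords(s, "C", rt)
  O <- atom_coords(s, "O", rt); H <- atom_coords(s, "H", rt)
  empty <- data.frame(donor = integer(0), acceptor = integer(0),
                      energy = numeric(0))
  if (n < 2L) return(empty)
  ok_ca <- !is.na(CA[, 1L])
  idx <- which(ok_ca)
  if (length(idx) < 2L) return(empty)
  D2 <- as.matrix(stats::dist(CA[idx, , drop = FALSE]))
  cand <- which(D2 < 9 & upper.tri(D2), arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  i <- idx[cand[, 1L]]; j <- idx[cand[, 2L]]
  # donor d, acceptor a; exclude d == a + 1 (peptide-bonded neighbour)
  pairs <- rbind(cbind(d = i, a = j)[i != j + 1L, , drop = FALSE],
                 cbind(d = j, a = i)[j != i + 1L, , drop = FALSE])
  d <- pairs[, 1L]; a <- pairs[, 2L]
  has <- !is.na(H[d, 1L]) & !is.na(N[d, 1L]) & !is.na(O[a, 1L]) & !is.na(C[a, 1L])
  d <- d[has]; a <- a[has]
  if (!length(d)) return(empty)
  dst <- function(P, Q) sqrt(rowSums((P - Q)^2))
  rON <- dst(O[a, , drop = FALSE], N[d, , drop = FALSE])
  rCH <- dst(C[a, , drop = FALSE], H[d, , drop = FALSE])
  rOH <- dst(O[a, , drop = FALSE], H[d, , drop = FALSE])
  rCN <- dst(C[a, , drop = FALSE], N[d, , drop = FALSE])
  E <- .KS_QQF * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  E[rON < .KS_MIN_DIST | rCH < .KS_MIN_DIST | rOH < .KS_MIN_DIST |
      rCN < .KS_MIN_DIST] <- -9.9
  E <- pmax(E, -9.9)
  hb <- data.frame(donor = d, acceptor = a, energy = E)
  hb <- hb[hb$energy < .KS_CUTOFF, , drop = FALSE]
  if (!nrow(hb)) return(empty)
  # at most the two best bonds per donor
  hb <- hb[order(hb$donor, hb$energy), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(hb)), hb$donor),
                        function(k) k[seq_len(min(2L, length(k)))]),
                 use.names = FALSE)
  hb <- hb[sort(keep), , drop = FALSE]
  rownames(hb) <- NULL
  hb
}

#' Assign eight-class secondary structure
#'
#' Computes hydrogen bonds, n-turn and bridge patterns and the Calpha
#' curvature, and assigns each residue one of `H, G, I, E, B, T, S, C` with
#' overlap priority `H > E > B > G > I > T > S > C`. The collapsed loop mask
#' is TRUE where the class is in `{C, T, S}` (none / turn / bend) -- the loop
#' definition used downstream.
#'
#' @param s a [protein_structure()].
#' @return object of class `secstruct_assignment`: a data.frame with one row
#'   per residue (`chain`, `seq_id`, `res_idx`, `aa`, `class8`, `loop`,
#'   `kappa`, `sense`, `segment`).
#' @export
assign_secstruct <- function(s) {
  if (!any(s$atoms$elety == "H")) s <- place_amide_hydrogens(s)
  rt <- residues(s)
  n <- nrow(rt)
  CA <- atom_coords(s, "CA", rt)
  seg <- .segment_ids(rt, CA)
  hb_df <- kabsch_sander_hbonds(s)
  hb <- matrix(FALSE, n, n)
  if (nrow(hb_df)) hb[cbind(hb_df$donor, hb_df$acceptor)] <- TRUE
  hbond <- function(d, a) {
    ok <- d >= 1L & d <= n & a >= 1L & a <= n
    out <- logical(length(d))
    out[ok] <- hb[cbind(d[ok], a[ok])]
    out
  }
  same_seg <- function(i, j) {
    ok <- i >= 1L & i <= n & j >= 1L & j <= n
    out <- logical(length(i))
    out[ok] <- seg[i[ok]] == seg[j[ok]]
    out
  }
  ii <- seq_len(n)
  # n-turns: H-bond from N-H(i+k) to C=O(i), within one segment
  turn <- list()
  for (k in 3:5) {
    turn[[k]] <- hbond(ii + k, ii) & same_seg(ii, ii + k)
  }
  at <- function(v, i) {
    ok <- i >= 1L & i <= n
    out <- logical(length(i)); out[ok] <- v[i[ok]]; out
  }
  mark_span <- function(starts, len) {
    m <- logical(n)
    for (p in starts) m[p:min(n, p + len - 1L)] <- TRUE
    m
  }
  # helices: two consecutive k-turns starting at i-1 and i
  isH <- mark_span(which(turn[[4L]] & at(turn[[4L]], ii - 1L)), 4L)
  isG <- mark_span(which(turn[[3L]] & at(turn[[3L]], ii - 1L)), 3L)
  isI <- mark_span(which(turn[[5L]] & at(turn[[5L]], ii - 1L)), 5L)
  # bridges (|i - j| >= 3, i-1/i+1 neighbours within i's segment)
  P <- matrix(FALSE, n, n); A <- matrix(FALSE, n, n)
  if (nrow(hb_df)) {
    ok_nb_prev <- c(FALSE, seg[-1L] == seg[-n])       # i ~ i-1
    ok_nb_next <- c(seg[-n] == seg[-1L], FALSE)       # i ~ i+1
    sh <- function(M, dr, dc) {
      # M shifted so that out[i, j] = M[i + dr, j + dc] (FALSE out of range)
      out <- matrix(FALSE, n, n)
      ri <- seq_len(n) + dr; ci <- seq_len(n) + dc
      vr <- ri >= 1L & ri <= n; vc <- ci >= 1L & ci <= n
      out[vr, vc] <- M[ri[vr], ci[vc]]
      out
    }
    HB <- hb  # HB[d, a]
    # parallel:     Hb(i-1, j) & Hb(j, i+1)  |  Hb(j-1, i) & Hb(i, j+1)
    P <- (sh(HB, -1L, 0L) & t(sh(HB, 0L, +1L))) |
         (t(sh(HB, -1L, 0L)) & sh(HB, 0L, +1L))
    # antiparallel: Hb(i, j) & Hb(j, i)      |  Hb(i-1, j+1) & Hb(j-1, i+1)
    A <- (HB & t(HB)) | (sh(HB, -1L, +1L) & t(sh(HB, -1L, +1L)))
    far <- abs(outer(ii, ii, "-")) >= 3L
    nb_ok <- outer(ok_nb_prev & ok_nb_next, ok_nb_prev & ok_nb_next, "&")
    P <- P & far & nb_ok
    A <- A & far & nb_ok
    P <- P | t(P); A <- A | t(A)
  }
  bridged <- function(M) rowSums(M) > 0
  laddered <- function(M) {
    out <- logical(n)
    idx <- which(M, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1L]; j <- idx[r, 2L]
      ext <- (i > 1L && any(M[i - 1L, max(1L, j - 1L):min(n, j + 1L)])) ||
             (i < n && any(M[i + 1L, max(1L, j - 1L):min(n, j + 1L)]))
      if (ext) out[i] <- TRUE
    }
    out
  }
  isE <- laddered(P) | laddered(A)
  isB <- (bridged(P) | bridged(A)) & !isE
  sense <- ifelse(bridged(A), "A", ifelse(bridged(P), "P", ""))
  # turns: residues strictly inside any n-turn span
  isT <- logical(n)
  for (k in 3:5) {
    for (p in which(turn[[k]])) {
      span <- (p + 1L):(p + k - 1L)
      span <- span[span <= n]
      isT[span] <- TRUE
    }
  }
  # bend: kappa computed from CA(i-2), CA(i), CA(i+2)
  kappa <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i <= 2L || i >= n - 1L) next
    if (!(same_seg(i - 2L, i) && same_seg(i, i + 2L))) next
    if (anyNA(CA[i - 2L, ]) || anyNA(CA[i, ]) || anyNA(CA[i + 2L, ])) next
    u <- CA[i, ] - CA[i - 2L, ]; v <- CA[i + 2L, ] - CA[i, ]
    kappa[i] <- vec_angle(u, v)
  }
  isS <- !is.na(kappa) & kappa > .BEND_KAPPA
  cls <- rep("C", n)
  cls[isS] <- "S"; cls[isT] <- "T"
  cls[isI] <- "I"; cls[isG] <- "G"
  cls[isB] <- "B"; cls[isE] <- "E"
  cls[isH] <- "H"
  out <- data.frame(chain = rt$chain, seq_id = rt$seq_id,
                    res_idx = rt$res_idx, aa = rt$aa, class8 = cls,
                    loop = cls %in% c("C", "T", "S"), kappa = kappa,
                    sense = sense, segment = seg, stringsAsFactors = FALSE)
  stopifnot(nrow(out) == n, identical(out$loop, out$class8 %in% c("C", "T", "S")))
  class(out) <- c("secstruct_assignment", "data.frame")
  out
}

#' Collapsed loop mask of an assignment
#'
#' TRUE exactly where the eight-class code is `C` (none), `T` (turn) or `S`
#' (bend).
#'
#' @param a a `secstruct_assignment`.
#' @return logical vector, one element per residue.
#' @export
loop_mask <- function(a) {
  stopifnot(inherits(a, "secstruct_assignment"))
  a$loop
}

#' Write a per-residue secondary-structure TSV
#'
#' @param a a `secstruct_assignment`.
#' @param path output path.
#' @export
write_secstruct_tsv <- function(a, path) {
  utils::write.table(
    a[, c("chain", "seq_id", "aa", "class8", "loop", "kappa")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.secstruct_assignment <- function(x, ...) {
  cat(sprintf("<secstruct_assignment> %d residues, %.1f%% loop\n",
              nrow(x), 100 * mean(x$loop)))
  cat(paste(x$class8, collapse = ""), "\n")
  invisible(x)
}
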