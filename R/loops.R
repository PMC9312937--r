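# Loop extraction under the none/turn/bend definition and pairing of
# experimental with predicted fragments under the 100%-sequence-identity
# contract. Loop spans are always defined on the experimental structure's
# assignment; the predicted structure contributes coordinates, confidence and
# its own secondary-structure classes over the same spans.

#' Extract contiguous loop regions from a masked structure
#'
#' Maximal runs of loop residues per chain, not crossing chain breaks or
#' backbone-incomplete residues; runs shorter than `min_len` are discarded.
#'
#' @param s a [protein_structure()].
#' @param mask either a `secstruct_assignment` for `s` or a logical vector of
#'   length equal to the residue count.
#' @param min_len minimum loop length in residues (default 3).
#' @return list of `loop_region` objects, in chain order. Each carries
#'   `parent_id`, `chain`, `res_idx` (global residue indices), `seq_ids`,
#'   `sequence`, `length` and `classes`.
#' @export
extract_loops <- function(s, mask, min_len = 3L) {
  rt <- residues(s)
  n <- nrow(rt)
  if (inherits(mask, "secstruct_assignment")) {
    a <- mask
    stopifnot(nrow(a) == n)
    mvec <- a$loop
    seg <- a$segment
    classes <- a$class8
  } else {
    if (length(mask) != n) stop("mask length does not match residue count")
    mvec <- as.logical(mask)
    seg <- .segment_ids(rt, atom_coords(s, "CA", rt))
    classes <- rep(NA_character_, n)
  }
  if (min_len < 1L) stop("min_len must be >= 1")
  run_id <- cumsum(c(TRUE, mvec[-1L] != mvec[-n] | seg[-1L] != seg[-n]))
  out <- list()
  for (rid in unique(run_id)) {
    idx <- which(run_id == rid)
    if (!mvec[idx[1L]] || length(idx) < min_len) next
    out[[length(out) + 1L]] <- structure(list(
      parent_id = s$id,
      chain = rt$chain[idx[1L]],
      res_idx = idx,
      seq_ids = rt$seq_id[idx],
      sequence = paste(rt$aa[idx], collapse = ""),
      length = length(idx),
      classes = classes[idx]
    ), class = "loop_region")
  }
  out
}

#' @export
print.loop_region <- function(x, ...) {
  cat(sprintf("<loop_region> %s chain %s %s-%s (%d res) %s\n", x$parent_id,
              x$chain, x$seq_ids[1L], x$seq_ids[x$length], x$length,
              x$sequence))
  invisible(x)
}

#' Pair experimental loops with the predicted structure
#'
#' For every experimental loop, the predicted fragment at the same author
#' seq_id span is located; pairs with any missing residue or sequence
#' mismatch are rejected with a warning. Loop spans come from the
#' experimental structure only. When a `secstruct_assignment` of the full
#' predicted structure is supplied, its classes restricted to the span are
#' recorded on the predicted side (needed by the change-in-SSE metric).
#'
#' @param exp_s experimental [protein_structure()].
#' @param exp_loops loops from [extract_loops()] on `exp_s`.
#' @param pred_s predicted [protein_structure()].
#' @param pred_assignment optional `secstruct_assignment` for `pred_s`.
#' @return list of `loop_pair` objects with elements `exp`, `pred`,
#'   `pair_id`.
#' @export
pair_loops <- function(exp_s, exp_loops, pred_s, pred_assignment = NULL) {
  rt_pred <- residues(pred_s)
  missing_chains <- setdiff(unique(vapply(exp_loops, `[[`, "", "chain")),
                            unique(rt_pred$chain))
  if (length(missing_chains)) {
    stop("predicted structure lacks chain(s): ",
         paste(missing_chains, collapse = ", "))
  }
  pred_key <- paste(rt_pred$chain, rt_pred$seq_id)
  pairs <- list()
  for (k in seq_along(exp_loops)) {
    lp <- exp_loops[[k]]
    idx <- match(paste(lp$chain, lp$seq_ids), pred_key)
    pair_id <- sprintf("%s:%s:%s-%s", lp$parent_id, lp$chain,
                       lp$seq_ids[1L], lp$seq_ids[lp$length])
    if (anyNA(idx)) {
      warning("span absent from prediction, pair skipped: ", pair_id)
      next
    }
    pred_seq <- paste(rt_pred$aa[idx], collapse = "")
    if (!identical(pred_seq, lp$sequence)) {
      warning("sequence mismatch, pair rejected: ", pair_id)
      next
    }
    pred_idx <- rt_pred$res_idx[idx]
    pred_lp <- structure(list(
      parent_id = pred_s$id, chain = lp$chain, res_idx = pred_idx,
      seq_ids = lp$seq_ids, sequence = pred_seq, length = lp$length,
      classes = if (!is.null(pred_assignment))
        pred_assignment$class8[pred_idx] else rep(NA_character_, lp$length)
    ), class = "loop_region")
    pairs[[length(pairs) + 1L]] <- structure(
      list(exp = lp, pred = pred_lp, pair_id = pair_id), class = "loop_pair")
  }
  pairs
}

#' Loop inventory table
#'
#' @param loops list of `loop_region` (or `loop_pair`, in which case the
#'   experimental side is tabulated and the pair id retained).
#' @return data.frame: `pair_id`/`loop_id`, `parent_id`, `chain`,
#'   `start_seq_id`, `end_seq_id`, `length`, `sequence`.
#' @export
loop_inventory <- function(loops) {
  rows <- lapply(loops, function(x) {
    if (inherits(x, "loop_pair")) {
      lp <- x$exp; id <- x$pair_id
    } else {
      lp <- x
      id <- sprintf("%s:%s:%s-%s", lp$parent_id, lp$chain, lp$seq_ids[1L],
                    lp$seq_ids[lp$length])
    }
    data.frame(pair_id = id, parent_id = lp$parent_id, chain = lp$chain,
               start_seq_id = lp$seq_ids[1L], end_seq_id = lp$seq_ids[lp$length],
               length = lp$length, sequence = lp$sequence,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a loop fragment as a PDB file
#'
#' Mirrors the downloadable loop-database format: each fragment becomes a
#' small standalone PDB file.
#'
#' @param s the parent [protein_structure()].
#' @param loop a `loop_region` from `s`.
#' @param path output path.
#' @export
write_loop_pdb <- function(s, loop, path) {
  sub <- s
  sub$atoms <- s$atoms[s$atoms$res_idx %in% loop$res_idx, , drop = FALSE]
  write_structure(sub, path)
}

# Coordinates of a loop fragment: one row per (residue, atom) in residue
# order. atom_set "backbone" = N, CA, C, O; "CA"; "heavy" = all non-H.
loop_coordinates <- function(s, loop, atom_set = c("backbone", "CA", "heavy")) {
  atom_set <- match.arg(atom_set)
  want <- switch(atom_set, backbone = c("N", "CA", "C", "O"), CA = "CA",
                 heavy = NULL)
  a <- s$atoms[s$atoms$res_idx %in% loop$res_idx, , drop = FALSE]
  if (is.null(want)) {
    a <- a[a$elety != "H", , drop = FALSE]
  } else {
    a <- a[a$elety %in% want, , drop = FALSE]
    cnt <- table(factor(a$res_idx, levels = loop$res_idx))
    if (any(cnt != length(want))) return(NULL)  # incomplete for this set
    a <- a[order(match(a$res_idx, loop$res_idx), match(a$elety, want)), ,
           drop = FALSE]
  }
  as.matrix(a[, c("x", "y", "z")])
}
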