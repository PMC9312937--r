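# Aggregate analyses over the per-loop metric table: distributions,
# length-stratified means with standard errors, linear fits with R^2,
# secondary-structure composition tables, representative-loop selection,
# ensemble variability and simple correlations.

#' Fraction of loop residues in a structure
#'
#' @param a a `secstruct_assignment` over a full structure.
#' @return fraction in \[0, 1\].
#' @export
loop_fraction <- function(a) {
  stopifnot(inherits(a, "secstruct_assignment"))
  if (!nrow(a)) stop("empty assignment")
  mean(a$loop)
}

#' Length-stratified summaries of a per-loop metric
#'
#' One row per distinct loop length with mean, standard error (sample sd /
#' sqrt(n); 0 when n = 1), min, max and count, sorted by length.
#'
#' @param rows per-loop metrics data.frame (from [loop_metrics()] rows).
#' @param field metric column name, e.g. `"rmsd"`, `"tm"`, `"delta_sse"`,
#'   `"mean_plddt"`.
#' @return data.frame: `length`, `n`, `mean`, `se`, `min`, `max`.
#' @export
stratify_by_length <- function(rows, field) {
  if (!nrow(rows)) stop("empty metrics table")
  if (!field %in% names(rows)) stop("unknown metric field: ", field)
  sp <- split(rows[[field]], rows$length)
  out <- data.frame(
    length = as.integer(names(sp)),
    n = vapply(sp, length, 1L),
    mean = vapply(sp, mean, 1),
    se = vapply(sp, function(v) if (length(v) > 1L)
      stats::sd(v) / sqrt(length(v)) else 0, 1),
    min = vapply(sp, min, 1),
    max = vapply(sp, max, 1)
  )
  out <- out[order(out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares linear fit with R^2
#'
#' @param x,y numeric vectors; `x` must contain at least 2 distinct values.
#' @return list of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `n`. Constant `y` yields `r_squared = 0` by convention.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 2L) stop("need at least 2 distinct x values")
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits; R^2 = 1 is a legitimate outcome here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (stats::sd(y) == 0 || !is.finite(r2)) r2 <- 0
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> y = %.4f x + %.4f, R^2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Length-trend regression, per-loop or on per-length bin means
#'
#' The study reports both styles: per-loop scatter fits and fits of
#' length-binned means (used for the split below/above-20-residue fits).
#'
#' @param rows per-loop metrics table.
#' @param field metric column name.
#' @param per_length if TRUE fit the per-length bin means, else the raw
#'   per-loop points.
#' @param min_length,max_length optional inclusive length window.
#' @return a `regression_fit`.
#' @export
length_trend_fit <- function(rows, field, per_length = FALSE,
                             min_length = -Inf, max_length = Inf) {
  rows <- rows[rows$length >= min_length & rows$length <= max_length, ,
               drop = FALSE]
  if (per_length) {
    s <- stratify_by_length(rows, field)
    linear_fit(s$length, s$mean)
  } else {
    linear_fit(rows$length, rows[[field]])
  }
}

.composition_levels <- c("none", "turn", "bend", "parallel_sheet",
                         "antiparallel_sheet", "alpha_helix", "pi_helix",
                         "three10_helix")

#' Secondary-structure composition of loop residues
#'
#' Fractions of the eight classes over all supplied loop-span residues,
#' normalised by the total residue count. Sheet residues (`E` and isolated
#' bridges `B`) are split into parallel/antiparallel by their ladder sense.
#'
#' @param classes character vector of eight-class codes over loop residues.
#' @param sense matching vector of ladder senses (`"P"`, `"A"` or `""`);
#'   sheet residues with unknown sense count as antiparallel.
#' @return data.frame `category`, `fraction` (sums to 1), with attributes
#'   `regular_fraction` (share of residues in `{H,G,I,E,B}`) and
#'   `helix_share` (share of that regular content that is helical).
#' @export
sse_composition <- function(classes, sense = rep("", length(classes))) {
  stopifnot(length(classes) == length(sense))
  n <- length(classes)
  if (!n) stop("no residues supplied")
  cat8 <- ifelse(classes == "C", "none",
          ifelse(classes == "T", "turn",
          ifelse(classes == "S", "bend",
          ifelse(classes %in% c("E", "B") & sense == "P", "parallel_sheet",
          ifelse(classes %in% c("E", "B"), "antiparallel_sheet",
          ifelse(classes == "H", "alpha_helix",
          ifelse(classes == "I", "pi_helix", "three10_helix")))))))
  frac <- table(factor(cat8, levels = .composition_levels)) / n
  out <- data.frame(category = .composition_levels,
                    fraction = as.numeric(frac), stringsAsFactors = FALSE)
  reg <- classes %in% c("H", "G", "I", "E", "B")
  attr(out, "regular_fraction") <- mean(reg)
  attr(out, "helix_share") <- if (any(reg))
    sum(classes[reg] %in% c("H", "G", "I")) / sum(reg) else NA_real_
  out
}

#' Representative loop per length
#'
#' For each requested length, the loop whose RMSD is closest to the mean
#' RMSD at that length; ties break to the lexicographically smaller pair id.
#'
#' @param rows per-loop metrics table.
#' @param lengths integer vector of loop lengths.
#' @return data.frame `length`, `pair_id`, `rmsd`, `mean_rmsd`.
#' @export
select_representatives <- function(rows, lengths) {
  out <- list()
  for (L in lengths) {
    sub <- rows[rows$length == L, , drop = FALSE]
    if (!nrow(sub)) {
      warning("no loops of length ", L, "; skipped")
      next
    }
    m <- mean(sub$rmsd)
    sub <- sub[order(abs(sub$rmsd - m), sub$pair_id), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(length = L,
                                          pair_id = sub$pair_id[1L],
                                          rmsd = sub$rmsd[1L], mean_rmsd = m,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Ensemble variability of loops versus prediction accuracy
#'
#' Given several experimental structures of one protein and a prediction,
#' compares (1) all pairwise experimental-experimental loop RMSDs (the
#' experimental range of accuracy) with (2) all prediction-experimental loop
#' RMSDs. Loop spans are defined on the first (reference) experimental
#' structure.
#'
#' @param exp_structures list of >= 2 experimental [protein_structure()]s
#'   sharing sequence over the evaluated spans.
#' @param pred predicted [protein_structure()].
#' @param min_len minimum loop length.
#' @param atom_set RMSD atom set.
#' @return list: `exp_exp`, `pred_exp` (data.frames with `pair_id`, `i`,
#'   `j`/`exp`, `rmsd`), `mean_exp_exp`, `mean_pred_exp`.
#' @export
ensemble_variability <- function(exp_structures, pred, min_len = 3L,
                                 atom_set = "backbone") {
  if (length(exp_structures) < 2L) {
    stop("need at least 2 experimental structures")
  }
  ref <- exp_structures[[1L]]
  a <- assign_secstruct(ref)
  loops <- extract_loops(ref, a, min_len = min_len)
  get_pairs <- function(s) pair_loops(ref, loops, s)
  k <- length(exp_structures)
  ee <- list(); pe <- list()
  for (li in seq_along(loops)) {
    frag <- function(s) {
      pl <- pair_loops(ref, loops[li], s)
      if (!length(pl)) return(NULL)
      loop_coordinates(s, pl[[1L]]$pred, atom_set)
    }
    coords <- lapply(exp_structures, frag)
    pc <- frag(pred)
    id <- loop_inventory(loops[li])$pair_id
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (is.null(coords[[i]]) || is.null(coords[[j]])) next
        ee[[length(ee) + 1L]] <- data.frame(
          pair_id = id, i = i, j = j,
          rmsd = kabsch_superpose(coords[[i]], coords[[j]])$rmsd)
      }
    }
    for (i in seq_len(k)) {
      if (is.null(coords[[i]]) || is.null(pc)) next
      pe[[length(pe) + 1L]] <- data.frame(
        pair_id = id, exp = i,
        rmsd = kabsch_superpose(coords[[i]], pc)$rmsd)
    }
  }
  ee <- do.call(rbind, ee); pe <- do.call(rbind, pe)
  list(exp_exp = ee, pred_exp = pe,
       mean_exp_exp = mean(ee$rmsd), mean_pred_exp = mean(pe$rmsd))
}

#' Pearson correlation with R^2
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list `r`, `r_squared`, `n`; zero variance in either vector yields
#'   NA with a warning.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, r_squared = NA_real_, n = length(x)))
  }
  r <- stats::cor(x, y)
  list(r = r, r_squared = r^2, n = length(x))
}

#' Binned profile of y against x
#'
#' Per-bin mean, standard error, min, max and count of `y` over fixed-width
#' bins of `x` (e.g. mean pLDDT as a function of TM-score).
#'
#' @param x binning variable.
#' @param y summarised variable.
#' @param width bin width (default 0.05).
#' @param origin left edge of the first bin (default 0).
#' @return data.frame `bin_lo`, `bin_hi`, `n`, `mean`, `se`, `min`, `max`.
#' @export
binned_profile <- function(x, y, width = 0.05, origin = 0) {
  stopifnot(length(x) == length(y))
  b <- floor((x - origin) / width + 1e-9)
  sp <- split(y, b)
  lo <- origin + as.numeric(names(sp)) * width
  out <- data.frame(
    bin_lo = lo, bin_hi = lo + width,
    n = vapply(sp, length, 1L),
    mean = vapply(sp, mean, 1),
    se = vapply(sp, function(v) if (length(v) > 1L)
      stats::sd(v) / sqrt(length(v)) else 0, 1),
    min = vapply(sp, min, 1),
    max = vapply(sp, max, 1)
  )
  out <- out[order(out$bin_lo), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.kyte_doolittle <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
  E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

#' Mean hydropathy of a sequence (Kyte-Doolittle)
#'
#' @param sequence one-letter amino-acid string; nonstandard letters are
#'   excluded from the mean with a message.
#' @return mean hydropathy index.
#' @export
hydropathy_index <- function(sequence) {
  aa <- strsplit(sequence, "")[[1L]]
  v <- .kyte_doolittle[aa]
  if (anyNA(v)) {
    message("excluding ", sum(is.na(v)), " nonstandard residue(s)")
    v <- v[!is.na(v)]
  }
  if (!length(v)) stop("no standard residues in sequence")
  mean(v)
}
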