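# End-to-end orchestration: from structure pairs to the per-loop metric
# table and every aggregate summary. Used by the analysis scripts, the test
# suite and the acceptance script alike.

#' Benchmark one experimental/predicted structure pair
#'
#' Runs the full per-pair pipeline: secondary-structure assignment of both
#' structures, loop extraction on the experimental side, 100%-identity
#' pairing, and all per-loop metrics.
#'
#' @param exp_s experimental [protein_structure()].
#' @param pred_s predicted [protein_structure()].
#' @param min_len minimum loop length (default 3).
#' @param atom_set RMSD atom set (default `"backbone"`).
#' @param d0_min TM-score d0 floor.
#' @return list: `metrics` (per-loop data.frame), `pairs`, `exp_assignment`,
#'   `pred_assignment`, `exp_loop_classes`/`pred_loop_classes` (+ senses)
#'   over all loop-span residues, and the two full-structure loop fractions.
#' @export
benchmark_pair <- function(exp_s, pred_s, min_len = 3L,
                           atom_set = "backbone", d0_min = 0.5) {
  ea <- assign_secstruct(exp_s)
  pa <- assign_secstruct(pred_s)
  loops <- extract_loops(exp_s, ea, min_len = min_len)
  pairs <- pair_loops(exp_s, loops, pred_s, pred_assignment = pa)
  metrics <- do.call(rbind, lapply(pairs, loop_metrics, exp_s = exp_s,
                                   pred_s = pred_s, atom_set = atom_set,
                                   d0_min = d0_min))
  span <- unlist(lapply(pairs, function(p) p$exp$res_idx))
  pspan <- unlist(lapply(pairs, function(p) p$pred$res_idx))
  list(metrics = metrics, pairs = pairs, exp_id = exp_s$id,
       exp_assignment = ea, pred_assignment = pa,
       exp_loop_classes = ea$class8[span], exp_loop_sense = ea$sense[span],
       pred_loop_classes = pa$class8[pspan], pred_loop_sense = pa$sense[pspan],
       exp_loop_fraction = loop_fraction(ea),
       pred_loop_fraction = loop_fraction(pa))
}

#' Run the benchmark over a set of structure pairs
#'
#' @param x either a data.frame manifest with columns `exp_path` /
#'   `pred_path`, or a `synthetic_benchmark` from [simulate_benchmark()], or
#'   a list of `list(exp =, pred =)` structure pairs. Pairs that fail are
#'   logged and skipped.
#' @inheritParams benchmark_pair
#' @return object of class `loop_benchmark`: `metrics` (all per-loop rows),
#'   `fractions` (per structure-pair loop fractions), `composition_exp` /
#'   `composition_pred` ([sse_composition()] tables over all loop residues),
#'   and `n_pairs_failed`.
#' @export
run_benchmark <- function(x, min_len = 3L, atom_set = "backbone",
                          d0_min = 0.5) {
  if (is.data.frame(x)) {
    pairs <- lapply(seq_len(nrow(x)), function(i) {
      list(exp = read_structure(x$exp_path[i], "experimental"),
           pred = read_structure(x$pred_path[i], "predicted"))
    })
  } else if (inherits(x, "synthetic_benchmark")) {
    pairs <- x$pairs
  } else pairs <- x
  if (!length(pairs)) stop("no structure pairs supplied")
  res <- list(); failed <- 0L
  for (p in pairs) {
    r <- tryCatch(benchmark_pair(p$exp, p$pred, min_len = min_len,
                                 atom_set = atom_set, d0_min = d0_min),
                  error = function(e) {
                    message("pair ", p$exp$id, " failed: ", conditionMessage(e))
                    NULL
                  })
    if (is.null(r)) failed <- failed + 1L else res[[length(res) + 1L]] <- r
  }
  if (!length(res)) stop("all structure pairs failed")
  metrics <- do.call(rbind, lapply(res, `[[`, "metrics"))
  fractions <- data.frame(
    id = vapply(res, `[[`, "", "exp_id"),
    exp_loop_fraction = vapply(res, `[[`, 1, "exp_loop_fraction"),
    pred_loop_fraction = vapply(res, `[[`, 1, "pred_loop_fraction"))
  ec <- unlist(lapply(res, `[[`, "exp_loop_classes"))
  es <- unlist(lapply(res, `[[`, "exp_loop_sense"))
  pc <- unlist(lapply(res, `[[`, "pred_loop_classes"))
  ps <- unlist(lapply(res, `[[`, "pred_loop_sense"))
  structure(list(metrics = metrics, fractions = fractions,
                 composition_exp = sse_composition(ec, es),
                 composition_pred = sse_composition(pc, ps),
                 n_pairs_failed = failed),
            class = "loop_benchmark")
}

#' @export
print.loop_benchmark <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<loop_benchmark> %d loops from %d structure pairs\n",
                     "  mean RMSD %.3f A | mean TM %.3f | mean dSSE %.2f%% | ",
                     "mean pLDDT %.1f\n"),
              nrow(m), nrow(x$fractions), mean(m$rmsd), mean(m$tm),
              mean(m$delta_sse), mean(m$mean_plddt)))
  invisible(x)
}

#' Write all summary tables of a benchmark run
#'
#' Emits the figure/table analogues as TSVs: per-loop metrics, loop-fraction
#' distribution, length distribution, length-stratified RMSD / TM / dSSE /
#' pLDDT, composition table, pLDDT-vs-TM binned profile, and the regression
#' fits.
#'
#' @param b a `loop_benchmark`.
#' @param dir output directory.
#' @return vector of written paths, invisibly.
#' @export
write_benchmark_tables <- function(b, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  m <- b$metrics
  comp <- data.frame(category = b$composition_exp$category,
                     experimental = b$composition_exp$fraction,
                     predicted = b$composition_pred$fraction)
  fits <- data.frame(
    response = c("rmsd", "tm", "delta_sse", "mean_plddt",
                 "rmsd_le20_binmeans", "rmsd_gt20_binmeans",
                 "tm_le20_binmeans", "tm_gt20_binmeans"),
    stringsAsFactors = FALSE)
  safe_fit <- function(...) {
    tryCatch(length_trend_fit(m, ...),
             error = function(e) list(slope = NA_real_, intercept = NA_real_,
                                      r_squared = NA_real_, n = 0L))
  }
  fl <- list(
    safe_fit("rmsd"), safe_fit("tm"),
    safe_fit("delta_sse"), safe_fit("mean_plddt"),
    safe_fit("rmsd", per_length = TRUE, max_length = 20),
    safe_fit("rmsd", per_length = TRUE, min_length = 21),
    safe_fit("tm", per_length = TRUE, max_length = 20),
    safe_fit("tm", per_length = TRUE, min_length = 21))
  fits$slope <- vapply(fl, `[[`, 1, "slope")
  fits$intercept <- vapply(fl, `[[`, 1, "intercept")
  fits$r_squared <- vapply(fl, `[[`, 1, "r_squared")
  fits$n <- vapply(fl, function(f) as.integer(f$n), 1L)
  paths <- c(
    w(m, "loop_metrics.tsv"),
    w(b$fractions, "loop_fractions.tsv"),
    w(as.data.frame(table(length = m$length), responseName = "n"),
      "length_distribution.tsv"),
    w(stratify_by_length(m, "rmsd"), "rmsd_by_length.tsv"),
    w(stratify_by_length(m, "tm"), "tm_by_length.tsv"),
    w(stratify_by_length(m, "delta_sse"), "delta_sse_by_length.tsv"),
    w(stratify_by_length(m, "mean_plddt"), "plddt_by_length.tsv"),
    w(comp, "composition.tsv"),
    w(binned_profile(m$tm, m$mean_plddt, width = 0.05), "plddt_vs_tm.tsv"),
    w(fits, "regressions.tsv"))
  invisible(paths)
}
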