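# loopbench

Loop regions — the parts of a protein that are neither α-helix nor β-strand —
are the least conserved, most flexible and hardest-to-predict parts of a
structure, and they are disproportionately involved in protein–protein
interactions and binding sites. `loopbench` is an R package for anyone who
wants to ask, loop by loop: *how well does a predicted model (for example an
AlphaFold 2 structure) reproduce the loops of an experimentally determined
reference?*

The package provides the full analysis pipeline as tested, reusable
functions, plus a deterministic synthetic-data generator so the whole study
runs end-to-end with no downloads:

* **Secondary structure, from scratch.** A Kabsch–Sander (DSSP-style)
  eight-class assignment: amide hydrogens placed geometrically, hydrogen
  bonds scored with the electrostatic energy
  `E = 0.084·332·(1/r(ON) + 1/r(CH) − 1/r(OH) − 1/r(CN))` kcal/mol
  (accepted below −0.5 kcal/mol), n-turn/bridge/ladder patterns, Cα-curvature
  bends, classes `H G I E B T S C`. A residue is a *loop* residue when its
  class is none/turn/bend (`C`/`T`/`S`).
* **Loop extraction and pairing.** Maximal loop runs (≥ 3 residues by
  default) defined on the experimental structure, paired with the predicted
  residues at the same author numbering under a strict 100% sequence-identity
  contract.
* **Per-loop metrics.** Kabsch-superposed RMSD (backbone atoms, local
  frame); TM-score `(1/L)Σ 1/(1+(dᵢ/d₀)²)` maximized over rigid
  superpositions with `d₀ = max(0.5, 1.24(L−15)^⅓ − 1.8)` and `L` the loop
  length; ΔSSE, the percent change in regular secondary-structure content;
  and mean pLDDT averaged over *atoms* (the per-residue confidence that
  AlphaFold-style models store in the B-factor column).
* **Aggregate statistics.** Length-stratified means with standard errors,
  per-loop and bin-mean linear fits with R² (including split fits at 20
  residues), eight-class composition tables, representative-loop selection,
  confidence-versus-accuracy profiles, Kyte–Doolittle hydropathy, and an
  ensemble-variability comparison of replicate experimental structures
  against a prediction.
* **Synthetic benchmark generator.** Paired experimental/predicted PDB
  files with a controlled loop-length law (~83% of loops under 10 residues),
  loop-fraction distribution around 40%, coordinate noise growing with loop
  length, spurious-helix injection growing with length, and a synthetic
  pLDDT anticorrelated with local error — byte-identical under a fixed seed.

See `vignettes/loopbench-methods.Rmd` for the models, parameter choices and
known limitations.

## Worked example

```r
library(loopbench)

spec <- synthetic_spec(n_proteins = 15, seed = 11)   # the study conditions
bm   <- simulate_benchmark(spec)                     # paired structures
b    <- run_benchmark(bm)                            # the full pipeline
print(b)
#> <loop_benchmark> 169 loops from 15 structure pairs
#>   mean RMSD 0.484 A | mean TM 0.749 | mean dSSE 1.06% | mean pLDDT 82.5

m <- b$metrics
mean(m$rmsd[m$length < 10])   #> 0.305  — short loops are predicted well
mean(m$rmsd[m$length > 20])   #> 1.700  — long loops much less so
100 * mean(m$delta_sse == 0)  #> 97.6   — % of loops with no spurious SSE
attr(b$composition_exp, "regular_fraction")  #> 0 — experimental loops are
                                             #    loop-only by construction
```

Each row of `b$metrics` is one loop pair: `pair_id`, `length`, `rmsd` (Å),
`tm` (0–1], `delta_sse` (%), `mean_plddt` (0–100). Short loops score high
(TM ≈ 0.82 below 10 residues here) and accuracy degrades with length, while
the synthetic confidence tracks the realised error — the behaviour the
pipeline is designed to measure and summarise.

The numbered drivers under `analysis/` run the same study against files on
disk and write every summary table under `results/`:

```sh
Rscript analysis/01_simulate.R     # benchmark set + truth record
Rscript analysis/02_benchmark.R    # per-loop metrics + summary tables
Rscript analysis/03_summaries.R    # regressions, representatives, correlations
Rscript analysis/04_ensemble.R     # replicate-vs-prediction RMSD comparison
```

To benchmark your own structures, point `run_benchmark()` at a two-column
manifest (`exp_path`, `pred_path`) of PDB files — predicted models must
carry pLDDT in the B-factor column and share residue numbering with the
reference.

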