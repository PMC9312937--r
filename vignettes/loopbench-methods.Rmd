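---
title: "Benchmarking predicted loop structures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking predicted loop structures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopbench)
```

# The problem

Loops — the protein regions that are neither α-helix nor β-strand — are the
hardest parts of a structure to predict: they are poorly conserved, often
flexible, and frequently missing from crystal structures. `loopbench`
evaluates how well a predicted model (for example an AlphaFold 2 structure,
with per-residue pLDDT confidence in the B-factor column) reproduces the
loop regions of an experimentally determined reference, loop by loop.

The unit of analysis is the *loop pair*: a contiguous run of loop residues
identified on the experimental structure, together with the residues at the
same author numbering in the prediction, under a strict 100%
sequence-identity contract. Four quantities are computed per pair:

* **RMSD** (Å) after an optimal local rigid superposition of the two
  fragments (Kabsch algorithm);
* **TM-score** in (0, 1], `(1/L) Σ 1/(1 + (dᵢ/d₀)²)` maximized over rigid
  superpositions, with `d₀ = max(0.5, 1.24·(L−15)^{1/3} − 1.8)` and `L` the
  loop length;
* **ΔSSE** (%), the change in regular secondary-structure content
  (classes H, G, I, E, B) from the experimental fragment to the predicted
  one;
* **mean pLDDT**, the arithmetic mean of the per-atom confidence over all
  atoms of the fragment (atom-weighted, not residue-weighted).

Aggregates follow: length-stratified means with standard errors, linear
trends with R², class-composition tables, representative-loop selection,
confidence-versus-accuracy profiles, and an ensemble-variability comparison.

# Secondary-structure assignment

Loops are defined through an eight-class secondary-structure assignment in
the Kabsch–Sander (DSSP) tradition, implemented from scratch:

1. **Amide hydrogens** are placed 1.0 Å from N along the previous residue's
   O→C direction; prolines and chain-start residues get none.
2. **Hydrogen bonds** are scored with the electrostatic energy
   `E = 0.084·332·(1/r(ON) + 1/r(CH) − 1/r(OH) − 1/r(CN))` kcal/mol over all
   donor/acceptor pairs within 9 Å Cα–Cα, excluding the donor directly
   following the acceptor; bonds are accepted below −0.5 kcal/mol, at most
   the two best per donor. Distances under 0.5 Å clamp the energy at −9.9.
3. **Patterns**: two consecutive n-turns (i→i+3/4/5) start a 3₁₀/α/π helix;
   parallel and antiparallel bridge patterns yield isolated bridges (B) and
   ladders (E); remaining residues inside a turn span become T; remaining
   residues with Cα curvature κ > 70° (measured at i from i−2 and i+2)
   become bends (S); everything else is none (C). Overlaps resolve with
   priority H > E > B > G > I > T > S > C.

A residue is a **loop residue** exactly when its class is C, T or S
(none/turn/bend). Chains are split into segments at chain-id changes,
backbone-incomplete residues and Cα–Cα gaps above 4.5 Å; no pattern crosses
a segment break, which keeps turns from spanning crystal-structure gaps.

Because every DSSP build differs slightly at class boundaries, the test
suite checks the *collapsed loop mask* against a reference DSSP
implementation (run once on generated fixtures, outputs stored as text)
and requires at least 95% per-residue agreement; on the shipped fixtures the
agreement is 98–100%. β-bulge absorption into ladders is not implemented,
which is one known source of residual class-level disagreement on real
structures.

# Metric computation choices

* **Superposition frame.** Loops are superposed locally, fragment on
  fragment. A whole-structure frame would mix loop error with domain
  placement error; the very small short-loop RMSDs typical of this kind of
  benchmark are only reproducible in the local frame.
* **RMSD atom set.** Backbone (N, CA, C, O) by default, with `CA` and
  `heavy` options; incomplete residues trigger a logged fall-back to CA.
* **TM-score normalization.** `L` is the loop's own length — the fragment
  is the target structure — and d₀ is floored at 0.5 Å, without which the
  formula is non-positive for all loops shorter than 22 residues (the vast
  majority).
* **TM-score search.** Seeds are Kabsch superpositions of all contiguous
  fragments of lengths L, L/2 and L/4 (≥ 4 residues), each refined by
  iterative re-superposition on the residues within a d₀-dependent cutoff
  (d₀ + 1.5 Å, at least 3.5 Å) until the subset stabilises. Because the
  score surface for short noisy fragments is multimodal, the seed set is
  augmented with closest-subset iterations (superpose on the m nearest
  residues, m = 3…6, until stable) and with the 24 proper rotations of the
  cube applied at the centroids; every seed receives a derivative-free
  polish of the score itself, and the best few are polished deeply. When
  the polished global superposition already scores ≥ 0.9 it is returned
  directly — in that regime the surface is unimodal and the measured gain
  from the full search never exceeded 5·10⁻⁴. The search provably returns
  at least the naive single-superposition score; tests require agreement
  within 10⁻³ with an independent exhaustive-start oracle.
* **ΔSSE classes.** Predicted classes are taken from the assignment of the
  *full* predicted structure restricted to the loop span, not from the
  isolated fragment — hydrogen-bond partners outside the span legitimately
  affect the classes. Experimental loop residues are all C/T/S by
  construction, so ΔSSE ≥ 0 on conforming data.
* **Degenerate inputs.** Collinear point sets flag the superposition as
  degenerate but still return a minimizer; constant responses define
  R² = 0; single-member length bins report a standard error of 0; ties in
  representative selection break to the smaller pair id.

# The synthetic generator

Real benchmark data for this task is a large download of experimental and
predicted structure pairs. The generator replaces it with fully synthetic
pairs so that every pipeline stage and every qualitative trend can be
exercised deterministically and offline. It emulates, by construction:

* a per-protein loop-residue fraction drawn from N(0.40, 0.06²), clamped to
  [0.2, 0.95] (proteins alternate α-helical scaffold segments with coil
  loops; helices are the only scaffold element because the dominant
  over-prediction mode being emulated is helical);
* loop lengths `3 + Geom(p = 0.2217)`, putting ≈ 83% of benchmark loops
  below 10 residues and ≈ 98.6% below 20, plus occasional 1–2 residue
  loops (8%) that the minimum-length filter removes;
* per-loop isotropic coordinate noise with RMS displacement
  `σ(L) = 0.047·L^{1.19}` Å — non-decreasing in loop length, anchored so
  that short loops (< 10 residues) average ≈ 0.33 Å RMSD and long loops
  (> 20) ≈ 2 Å, with scaffold residues at 0.05 Å;
* spurious helix injection with probability `min(0.95, 0.018·(L − 5))` per
  loop: a sub-span of 6–10 residues is rebuilt with ideal helical torsions,
  anchored at the preceding residue (continuity is kept upstream of the
  span; the downstream junction may break, which is tolerated because
  spans never cross the junction);
* synthetic confidence `clamp(55 + 40·e^{−disp} + N(0, 2.5²), 0, 100)`
  written to every atom's B-factor, where `disp` is the residue's realised
  mean displacement — a decreasing function of local error, which is all
  the downstream confidence analyses require.

Coil torsions are sampled from four non-helical, non-strand basins (around
polyproline-II, extended, bridge and near-PPII regions, ±15° uniform
jitter); isolated coils built this way assign 0% regular structure, which
underwrites the tautology that experimental loop residues show 0%
helix/sheet content. Sequences are poly-Ala by default
(`sequence_mode = "random"` draws uniformly over the 19 non-proline
residues, needed for hydropathy analyses).

Noise is applied *after* loop spans are fixed on the clean structure, so
truth records remain valid and pairing is 100%-identity by construction.
All randomness flows from a single integer seed through per-protein
sub-seeds; the same spec reproduces byte-identical files.

## What the generator does not emulate

Synthetic noise is isotropic and residue-independent within a loop, whereas
real prediction error is structured (hinge motions, register shifts,
well-predicted stems with divergent tips). Two consequences are worth
keeping in mind. First, the TM-score of long noisy loops is lower than for
real predictions of equal RMSD, because no sub-fragment is predicted well.
Second, passing trend tests here demonstrates that the *pipeline* measures
what it should — not that any particular predictor behaves this way on real
proteins. There are also no side chains beyond the backbone, no β-sheet
scaffolds, no missing residues and no alternate conformations in the
synthetic chains (the parser handles all of these for real inputs).

# Problem sizes and determinism

The shipped analysis scripts use 60 proteins (≈ 700 loops); the acceptance
script uses 90; the parameter-recovery test uses 45 proteins (≈ 500 loops,
the size at which the recovery bounds are specified). These sizes were
chosen as the smallest at which the length-stratified trends are stable
across seeds. Every random step takes an explicit seed; re-running any
script with the same seed reproduces identical tables.

# Known limitations

* The assignment omits β-bulges and polyproline-II classes; agreement with
  any specific DSSP binary is therefore bounded away from 100% at the
  class level (the collapsed loop mask is what the pipeline relies on).
* Minimum loop length defaults to 3 residues; `min_len = 1` is available
  for exploring the full length distribution.
* Pairing is by residue numbering under exact identity — there is
  deliberately no alignment machinery, so renumbered predictions must be
  renumbered before use.
* The TM-score search is a global optimisation heuristic; it is validated
  against a brute-force oracle on small fragments, but third-decimal
  agreement with any specific external TM-score binary is not guaranteed.
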