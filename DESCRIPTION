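Package: loopbench
Title: Benchmarking Predicted Protein Loop Structures Against Experimental References
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how well predicted protein structures (for
    example AlphaFold 2 models, with per-residue pLDDT confidence stored in the
    B-factor column) reproduce the loop regions of experimentally determined
    structures. Provides a from-scratch DSSP-style eight-class secondary
    structure assignment built on Kabsch-Sander hydrogen-bond energies, loop
    extraction under the none/turn/bend definition, 100%-identity pairing of
    experimental and predicted loop fragments, per-loop similarity and
    confidence metrics (Kabsch-superposed RMSD, TM-score, change in regular
    secondary-structure content, atom-averaged pLDDT), length-stratified and
    ensemble-variability summaries, and a deterministic synthetic generator of
    paired structures so the whole analysis runs without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
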