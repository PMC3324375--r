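Package: casp3scan
Title: Caspase-3 Cleavage-Site Prediction with Position-Specific Scoring Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts caspase-3 cleavage sites in protein sequences with a
    position-specific scoring-matrix model over a 14-residue window (P9-P5')
    centred on a candidate aspartate. Four base-2 log-odds matrices are
    combined: a plain log-odds matrix against natural amino-acid frequencies,
    a background-subtracted matrix built from uncleaved-aspartate windows,
    and a pair of sub-pattern matrices selected by the residue at P4. The
    package covers the full workflow: deriving positive and negative peptide
    datasets from annotated substrates, fitting and persisting models,
    scanning and proteome-scale screening, repeated k-fold cross-validation
    with ROC/AUC and optimal-cutoff selection, window-size sweeps, flanking
    amino-acid composition analysis, and a seeded synthetic-substrate
    simulator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
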