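Package: glycoPSSM
Title: Position-Specific Scoring Matrix Prediction of O-GlcNAc Glycosylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies position-specific amino-acid scoring matrices
    for prediction of O-GlcNAc transferase (OGT) glycosylation sites on
    serine/threonine residues of intrinsically disordered protein regions.
    Peptide windows centered on S/T residues are scored by summing matrix
    entries for the flanking residues; the matrix is trained by randomized
    hill climbing against a separation objective (the matrix assessment
    score, MAS) computed from the score distributions of a positive and a
    negative peptide set. Also provides dataset diagnostics (positional
    amino-acid frequency matrices, exact-binomial compositional-bias tests),
    confusion-matrix evaluation of site predictions, point-mutation
    utilities for compositional mutant design, a synthetic peptide-set
    generator with planted compositional biases for parameter-recovery
    benchmarking, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
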