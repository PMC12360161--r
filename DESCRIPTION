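Package: phos1433
Title: Prediction of 14-3-3 Binding Phosphopeptides with Ensemble Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of 14-3-3 protein binding for
    phosphoserine/phosphothreonine peptides. Implements 15-residue binding
    window construction from protein sequences, four numeric peptide
    encodings (one-hot, learnable-embedding token ids, BLOSUM62 with a
    phospho flag, and physico-chemical descriptors), three small neural
    classifiers (multilayer perceptron, 1-D convolutional network, gated
    recurrent unit) trained with early stopping on validation F1, an
    averaging ensemble with majority vote, leakage-aware stratified
    cross-validation splitting with an edit-distance filter, a
    positional-shuffle interpretation study, a prospective phosphosite
    screening pipeline, and a motif-planted synthetic data generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
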