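Package: plastidstack
Title: Stacked Ensemble Prediction of Protein Subplastid Localization and Origin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies plastid proteins as nuclear- or plastid-encoded and
    predicts their subplastid localization (envelope, stroma, thylakoid
    membrane, thylakoid lumen) together with the Sec/Tat import pathway for
    lumenal proteins. Sequences are represented by binary presence/absence of
    gapped amino-acid n-grams, filtered with an exact permutation test
    (hypergeometric QuiPT), and fed to task-specific random forests; Sec and
    Tat targeting signals are scored with profile hidden Markov models built
    from signal alignments. A higher-level model stacks the lower-level
    outputs, optionally with conditionally restricted routing. The package
    also provides Needleman-Wunsch identity based homology reduction and
    partitioning of sequence datasets, a labelled synthetic sequence
    generator emulating the targeting-signal structure of the eight classes,
    and repeated stratified cross-validation with Cohen's kappa, Hand-Till
    multiclass AUC (AU1U) and class-specific accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    ranger,
    nnet,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
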