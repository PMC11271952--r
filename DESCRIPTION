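Package: attnrep
Title: Attentional Modulation of Working- and Long-Term-Memory Representations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for selective-attention fMRI
    studies with retro-cue designs. Generates seeded synthetic cohorts
    (behavioral recognition tables and ROI-level BOLD runs with injectable
    attentional gain, distractor suppression and pair-specific pattern
    repulsion), estimates single-trial response maps by the least-squares
    separate method with double-gamma HRF designs and motion/FD censoring,
    decodes stimulus-category evidence with localizer-trained L2-regularized
    one-vs-rest logistic classifiers under leave-one-run-out validation,
    computes matched within-trial vs between-trial pattern-similarity
    statistics with Fisher z transforms and robust brain-behavior
    correlations, and provides group statistics (paired tests, two-way
    repeated-measures ANOVA, Benjamini-Hochberg FDR, within-subject error
    bars).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Classification, fMRI
RoxygenNote: 7.3.3
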