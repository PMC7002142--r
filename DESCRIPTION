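Package: plexsig
Title: Multiplexed Cytokine and Phosphoprotein Panel Analysis via Rotated PLS-DA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Supervised multivariate analysis of multiplexed bead-panel
    (Luminex-style) cytokine and phosphoprotein measurements. Provides a
    SummarizedExperiment-based container for sample-by-analyte panels, a
    preprocessing chain (linear-range exclusion, z-scoring, design-aware
    batch-effect removal, iterative PCA/Mahalanobis outlier rejection),
    NIPALS PLS-DA with an orthogonal rotation of the LV1-LV2 plane that
    maximizes group separation, leave-one-out loading-stability envelopes,
    label-permutation significance testing, univariate follow-up statistics
    (one-way ANOVA with Dunnett or Tukey post hoc tests, pooled and Welch
    t tests, control-normalized fold-change contrasts with Holm-Sidak
    correction), FDR-thresholded cross-animal correlation networks, and a
    seeded synthetic-panel generator with recorded ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mvtnorm,
    knitr,
    rmarkdown
VignetteBuilder: knitr
biocViews: Proteomics, Software, MultipleComparison, BatchEffect
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
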