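Package: mitoprofiler
Title: Multiparametric Phenotypic Profiling of Mitotic-Error Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for image-based RNAi screens
    that link mitotic errors to DNA damage in daughter cells. Provides a
    synthetic-screen generator with full ground truth (single-cell feature
    tables, 16-bit nuclear images, time-lapse trajectories), nuclear
    segmentation and top-hat focus detection, per-cell logistic-regression
    ensemble probability scoring against control cells with ROC-ranked
    model selection and leave-one-replicate-out validation, a per-siRNA
    statistics panel (confidence intervals, Kolmogorov-Smirnov normality
    flag, Mann-Whitney U, Hedges' g, AUC, DeLong model comparison),
    k-means phenotypic clustering with silhouette-based model selection,
    and temporal profiling of mitotic-error versus DNA-damage onset from
    time-lapse trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    cluster,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
biocViews: CellBasedAssays, Classification, Clustering, Software
RoxygenNote: 7.3.3
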