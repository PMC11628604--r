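Package: gliaQuant
Title: Quantitative Histology of Amyloid Plaques and Plaque-Associated Microglia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures amyloid-plaque morphology and microglial organisation in
    multi-channel fluorescence fields of view. Provides a calibrated synthetic-image
    and cohort generator with ground truth; a trainable multi-scale random-forest
    pixel classifier; plaque instance segmentation with grey-level co-occurrence
    texture (Angular Second Moment compactness); microglia instance segmentation by
    weighted fusion of Euclidean distance transforms followed by a seeded watershed;
    per-cell morphometrics (convex territory, skeleton process length,
    nearest-neighbour clustering) and the 5 micron plaque-association rule;
    single-molecule pulldown (SiMPull) spot counting; and the statistical layer used
    to analyse such cohorts: dose-response regression, confounder-adjusted multiple
    regression, ANOVA with Tukey contrasts, linear and binomial mixed-effects
    models, and an exact multi-set intersection test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    randomForest,
    lme4,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, CellBiology, Spatial, Classification
RoxygenNote: 7.3.3
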