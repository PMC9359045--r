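Package: hdadose
Title: Hierarchically Dense Attention U-Nets for 3D Radiotherapy Dose Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Knowledge-based planning tools for predicting 3D radiotherapy dose
    distributions on head-and-neck anatomy. Implements hierarchically dense
    3D U-nets with soft attention gates (HD, attention and HDA variants), a
    differentiable sigmoid approximation of the dose-volume histogram (DVH)
    used as a weighted training objective alongside voxelwise MSE, a CPU
    training loop with Adam and best-validation-epoch model selection, a
    synthetic head-and-neck phantom generator for fully reproducible cohorts,
    and the standard plan-quality evaluation suite (D99/D98/D95 coverage,
    Dmax, homogeneity H1/H2, conformity index and van't Riet conformation
    number, per-structure mean dose error, Vx, and two-tailed t-test
    comparisons between methods). Volumes are exchanged as NIfTI-1 files or
    as the sparse per-case CSV layout used by the OpenKBP challenge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
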