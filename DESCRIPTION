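Package: growthpls
Title: Growth-Informed Partial Least Squares for Microbial LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved multivariate analysis of binned LC-MS metabolomic
    profiles from microbial cultures. Implements the full chemometric chain:
    asymmetric-least-squares (Whittaker) baseline correction, total-area
    normalization, generalized-log transformation, autoscaling and pooled-QC
    filtering; growth-informed response vectors built from colony diameters;
    NIPALS partial least squares regression and discriminant analysis with
    leave-one-out cross-validation, permutation testing, VIP scoring and ROC
    assessment; trend classification and an induced-metabolite decision rule
    comparing fed and control cultures; and formula-based monoisotopic mass
    annotation with adduct and biotransformation mass-shift matching. Includes
    a synthetic-data generator that emulates a two-group, five-day fungal
    time-course design with planted ground truth for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    patchwork,
    withr
Config/testthat/edition: 3
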