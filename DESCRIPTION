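Package: midvif
Title: Collinearity Diagnostics and Bias Simulation for Event-Related fMRI Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying the impact of collinearity on contrast
    estimates in event-related fMRI general linear models. Implements
    contrast efficiency, the traditional variance inflation factor (tVIF)
    and a contrast-based variance inflation factor (cVIF) that is invariant
    to model reparameterization; a synthetic Monetary Incentive Delay (MID)
    task generator emulating the ABCD study trial structure with an
    adaptive probe-duration staircase; an omitted-regressor bias simulation
    framework measuring bias, type-I error and power of contrast estimates
    under alternative first-level models; and group-level machinery
    including precision-weighted run combination, percent-signal-change
    scaling, Cohen's d, and a site-stratified sign-flip cluster-extent
    permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    yaml
Config/testthat/edition: 3
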