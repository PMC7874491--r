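Package: t2dcvd
Title: Cardiovascular Disease Phenotyping in Type 2 Diabetes Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable phenotyping pipeline for estimating the prevalence of
    cardiovascular disease (CVD) among persons with type 2 diabetes (T2D) in
    German statutory health insurance (SHI) claims data. Implements a
    four-criterion claims-based T2D case-identification algorithm with an
    unspecific-diabetes (E14) exclusion, executable CVD definitions as
    ICD-10-GM/OPS prefix code sets under narrow and wide variants and
    configurable observation windows, period-prevalence estimation with Wald
    confidence intervals, stratified tables and population extrapolation, and
    a synthetic SHI claims generator with known ground truth so that every
    stage is testable without access-restricted real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
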