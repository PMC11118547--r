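Package: seqgauge
Title: Gauge Fixing for One-Hot Models of Sequence-Function Relationships
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for constructing, projecting, and interpreting one-hot
    linear models of sequence-function relationships (additive, pairwise,
    all-order, and general hierarchical interaction models). Implements the
    two-parameter family of linear gauges built from tensor products of
    single-position gauge spaces, including the trivial, Euclidean,
    equitable, zero-sum, hierarchical, wild-type, and generalized wild-type
    gauges, as well as arbitrary linear gauges defined by penalization
    matrices. Hierarchical (ANOVA-like) gauges support closed-form
    conditional means, variance decomposition by interaction order, and
    truncation of models to local additive approximations within regions of
    sequence space. Includes a synthetic-landscape simulator and a
    least-squares fitter for sequence-activity tables.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    MASS,
    tidyr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
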