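Package: phcquality
Title: Composite Quality Scores for Primary Health Care from Binary Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds composite quality-of-care scores for primary health care
    (PHC) from binary quality indicators organised in a three-domain,
    thirteen-sub-domain framework (PHC system, clinical care, user
    experience). Sub-domain and domain scores on [0, 1] are computed either
    as arithmetic means of indicators or, for clinical-care instruments, via
    a dichotomous Rasch (one-parameter logistic IRT) model estimated by
    marginal maximum likelihood with an EM algorithm and Gauss-Hermite
    quadrature, with expected-a-posteriori ability scoring. Includes
    internal-consistency reliability (Cronbach's alpha), multiple imputation
    by chained equations with Rubin pooling, subgroup summaries and
    regression with cluster-robust standard errors, a linked synthetic-data
    generator for patients, providers, chart abstractions and a follow-up
    registry, and a one-call pipeline producing a reproducible report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lmtest,
    nnet,
    pracma,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
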