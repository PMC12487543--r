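Package: motomort
Title: City-Level Motorcyclist Mortality Analysis with Garbage-Code
    Redistribution and Negative Binomial Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ecological analyses of motorcyclist road-traffic
    mortality across cities: classification of ICD-10 causes of death and
    stratified multinomial redistribution of ill-defined and partially
    defined external causes, completeness-corrected person-years, direct
    age standardization against the WHO world standard population,
    negative binomial regression with a city random intercept fitted by
    adaptive Gauss-Hermite quadrature with a cluster-robust variance
    estimator, and pooling of estimates across redistribution draws by
    Rubin's rule. Includes a synthetic multi-country data generator with
    known ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    sandwich,
    statmod,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmmTMB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
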