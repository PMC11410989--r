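Package: grtest
Title: Global Randomization Test for Covariate Balance of Genetic Instruments
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Falsification testing for the exclusion restriction and independence
    assumptions of Mendelian randomization. Implements a permutation test of joint
    covariate balance against a genetic instrument (binary exposure group, SNP
    dosage, or continuous genetic risk score) using a generalized Mahalanobis
    distance as the global balance statistic, together with comparator tests based
    on per-covariate regression with Bonferroni or effective-number-of-tests
    correction and a maximum-r2 permutation test. Also provides weighted genetic
    risk score construction, per-SNP randomization filtering of horizontally
    pleiotropic variants, and reproducible simulation studies of selection
    (collider) bias and horizontal pleiotropy with rejection-rate and Monte Carlo
    standard error reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    jsonlite,
    yaml,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
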