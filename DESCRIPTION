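Package: mixtcc
Title: Mixed Tukey MEWMA-MA Control Charts and Run-Length Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of moving-average (MA), modified exponentially
    weighted moving-average (MEWMA) and mixed MA/MEWMA control charts for
    individual observations, together with their nonparametric Tukey variants
    whose control limits are built from quartiles and the interquartile range.
    Includes a compiled Monte Carlo run-length engine for average, standard
    deviation and median run length (ARL, SDRL, MRL), calibration of
    control-limit coefficients to a target in-control ARL, expected ARL (EARL)
    over shift ranges, integral-equation and closed-form run-length oracles,
    Phase I / Phase II monitoring of univariate series, and generators for
    particulate-matter-like surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
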