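Package: eemviva
Title: Cell Viability from Excitation-Emission Fluorescence via PARAFAC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating cell-culture viability from
    excitation-emission matrix (EEM) fluorescence. Builds masked EEM cubes
    on an acquisition wavelength grid, fills the Rayleigh-scatter and
    unmeasured triangle, fits non-negative trilinear PARAFAC models by
    alternating least squares with exact non-negative least-squares
    subproblems, selects the number of components by residual and
    split-half analysis with Tucker congruence matching, regresses MTT
    viability on component scores with leave-one-out cross-validation,
    and compares dose groups by one-way ANOVA with Tukey HSD post hoc
    tests. Includes a synthetic-data generator emulating a two-cell-line,
    six-dose, twelve-replicate fluorescence study design so the whole
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
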