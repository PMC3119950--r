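Package: elqiso
Title: Isoeffect Calculations with the Linear-Quadratic and Extended
    Linear-Quadratic Cell-Survival Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for radiobiological isoeffect analysis with the
    two-parameter linear-quadratic (LQ) and three-parameter extended
    linear-quadratic (ELQ) cell-survival models.  The ELQ generalises the
    dose-protraction-modified LQ (constant-dose-rate Lea-Catcheside factor)
    and exhibits linear log-survival at high dose, making it suitable for
    hypofractionation and stereotactic dose ranges.  The package fits both
    models to clonogenic dose-survival data by weighted nonlinear least
    squares under a proportional-standard-deviation error model (with the
    conventional negative-alpha refit rule), reports weighted sums of
    squared residuals and percentage parameter uncertainties, solves
    isoeffect equivalences (closed form for LQ, bracketed root finding for
    the implicit ELQ relation), builds isoeffect curves with uncertainty
    bands, and generates synthetic survival datasets with proportional
    multiplicative noise for validation studies.  A small command-line
    interface ties the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
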