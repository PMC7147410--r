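Package: cumfp
Title: Cumulative False-Positive Burden of Repeated Non-Invasive Cancer Screening
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A deterministic annual-cycle state-transition (Markov) cohort
    model of the cumulative false-positive rate in repeated non-invasive
    colorectal-cancer screening, together with an exact closed-form
    survivorship-weighted oracle and a calibration routine that reconstructs
    the cohort's neoplasia-free survivorship curve from published anchor
    values. Supports scenario grids over starting age, screening interval and
    test specificity, a conditional-dependence sensitivity variant in which
    the false-positive probability drops after a prior true-negative result,
    and reporting under two denominators (per 100,000 alive at age 50 and per
    100,000 neoplasia-free at age 50).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
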