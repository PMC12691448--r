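Package: pdl1dyn
Title: Dynamic PD-L1 Regulation in Tumor-Immune Checkpoint Therapy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mechanistic ordinary-differential-equation models of combination
    immunotherapy with the immunocytokine NHS-muIL12 and the anti-PD-L1
    antibody Avelumab in syngeneic mouse tumors. Implements the four-state
    tumor/T-cell/drug system with impulsive bolus dosing, an optional fifth
    state for dynamically regulated functional PD-L1 expression (adaptive
    immune resistance), per-arm constant-epsilon and global dynamic-epsilon
    trajectory fitting by bounded multistart nonlinear least squares, RSS/AIC
    model comparison, local sensitivity analysis, and a synthetic study
    generator with parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
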