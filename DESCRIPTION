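Package: simexipw
Title: SIMEX-Corrected Inverse Probability Weighting with Confounder Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimation of the average treatment effect by stabilized
    inverse-probability weighting when confounders are contaminated by
    classical additive measurement error and may include spurious variables.
    Implements a five-step procedure: simulation-extrapolation (SIMEX)
    correction of the treatment-model coefficients, penalized variable
    selection (LASSO, SCAD, MCP, elastic net) on the corrected coefficients,
    and SIMEX-extrapolated Hajek weighting for the treatment effect, with
    bootstrap variance and p-value. The measurement-error covariance can be
    supplied directly, estimated from replicate surrogate measurements, or
    estimated from an external validation sample. Includes a synthetic-data
    generator emulating the assumed causal and error structure.
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
    MASS,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
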