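Package: credassign
Title: Credit Assignment in Trial-by-Trial Motor Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of credit assignment during motor
    adaptation to viscous curl force-fields. Implements two trial-by-trial
    state-space learning rules over movement direction -- plan-referenced
    (updates centred on the planned movement direction) and
    motion-referenced (updates centred on the actually experienced
    direction) -- with local Gaussian motor primitives, a closed-loop
    reaching simulator, generators for interference and shifted-target
    training schedules, a synthetic-subject data generator, and the
    error-clamp regression pipeline that turns measured lateral force
    profiles into adaptation coefficients, generalization patterns and
    learning-curve summaries.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
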