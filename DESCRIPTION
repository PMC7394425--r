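Package: handloc
Title: Analysis of Proprioceptive Hand-Landmark Localization Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing proprioceptive localization errors of hand
    landmarks measured with the hand Localization Task. Computes trial-wise
    systematic error vectors and their medio-lateral and proximo-distal
    components, inter-trial phase clustering (ITPC) indices of angle
    consistency within and between subjects, hand-structure estimation ratios
    (perceived/actual finger length and hand width), and a principal-component
    decomposition of shared error sources with component removal. Includes
    spatial preprocessing (unit conversion, knuckle-line alignment,
    Mahalanobis/chi-square outlier exclusion), mixed-effects and Gamma GLM
    inference stages, and a synthetic-data engine that generates localization
    datasets with configurable per-landmark error magnitude, direction and
    angle consistency, multi-level noise, and proximal drift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    tools,
    utils,
    lme4,
    lmerTest,
    emmeans,
    car,
    generics
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr
Config/testthat/edition: 3
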