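Package: cnmuss
Title: Curve-Number Runoff, MUSS Erosion and Surface-Water Exposure
    Mitigation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale re-implementation of the runoff and erosion
    machinery used in regulatory pesticide exposure modelling: the SCS
    curve-number (CN) rainfall-runoff relation with closed-form event-wise
    CN inversion and precipitation-weighted averaging, the MUSS event
    soil-loss equation with the 2-mm daily segmentation rule for peak
    runoff rate, whole-season simulation over daily weather, inverse
    calibration of the seasonal CN and the MUSS C-factor against measured
    totals, treatment-comparison reduction statistics (percent reductions,
    CN point deltas, relative C-factors, population-SD summary blocks),
    and the FOCUS-stream PECsw mitigation-correction procedure for
    edge-of-field surface-water concentrations. A seeded synthetic trial
    generator provides ground-truth weather and event tables so every
    pipeline stage is testable end to end.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
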