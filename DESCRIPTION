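Package: phvalid
Title: Validation of Maturity-Offset Prediction Equations Against
    Preece-Baines Age at Peak Height Velocity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates longitudinal growth cohorts with known age at peak
    height velocity (APHV), fits the Preece-Baines Model 1 to serial
    stature to estimate observed APHV, applies published maturity-offset
    prediction equations (Moore and Mirwald forms), and runs the standard
    evaluation battery for such predictions: chronological-age and
    years-from-PHV binning, early/average/late maturity classification,
    bias summaries, percentage-within-band hit rates, Bland-Altman
    agreement regressions and intra-individual spread of predicted APHV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
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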