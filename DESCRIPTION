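Package: feednirs
Title: NIRS Calibration of Feed Energy by Modified Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics workflow for calibrating near-infrared reflectance
    spectra of feed ingredients against digestible and metabolizable energy
    references for growing pigs. Provides scatter-correction (SNV, detrend,
    multiplicative scatter correction variants) and gap-segment derivative
    pre-treatments, modified partial least squares (MPLS) regression with
    cross-validated factor selection, global-H and T outlier elimination,
    grid search over pre-treatment combinations, standard chemometric
    evaluation statistics (SEC, SECV, SEP, RPD), the Noblet-Perez
    energy-prediction equations, and a synthetic corn dataset generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
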