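Package: crashtriage
Title: Occupant Injury Risk Estimation for Frontal Crashes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for estimating occupant injury severity in full-frontal
    vehicle crashes. Generates idealized crash pulses and lumped-parameter
    occupant responses under varying collision speed, seatbelt use and
    airbag deployment time; computes the Head Injury Criterion (HIC36) and
    the Combined Thoracic Index (CTI); maps both criteria to Abbreviated
    Injury Scale (AIS) severity bands; trains a three-layer feedforward
    neural network predicting head and chest AIS from delta-v, belt status
    and deployment time; and validates predictions against event data
    recorder (EDR) style records with confusion matrices and ROC/AUC
    analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
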