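Package: iliorisk
Title: Iliofemoral Vascular Complication Risk Assessment for Transfemoral TAVR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies iliofemoral artery tortuosity and calcification from
    3D vessel centerlines for pre-procedural planning of transfemoral
    transcatheter aortic valve replacement (TF-TAVR). Implements curve
    detection on resampled centerlines, the Cedars-Sinai Index (CSI = sum of
    curve angles x number of curves / minimal lumen diameter), the
    sheath-to-femoral-artery ratio (SFAR), calcification categories I-IV, the
    plaque-on-a-curve free-lumen realignment, and a two-step threshold tree
    classifying patients as high or low risk of iliofemoral vascular
    complication. Provides the cohort statistics used to derive and validate
    such a model (univariate screening, minimum-AIC logistic selection,
    2:1 caliper propensity matching, Gini recursive partitioning, ROC with
    DeLong intervals, calibration slope) and a synthetic vessel and cohort
    simulator so the whole pipeline can be exercised without patient CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    pROC
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
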