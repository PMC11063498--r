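Package: ipreface
Title: Intrapartum Fetal Acidemia Scoring from Cardiotocography Decelerations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the iPREFACE score, an integrated index that predicts
    fetal acidemia from the five-tier (JSOG) risk levels of fetal heart rate
    decelerations observed in a 30-minute cardiotocography window, in both the
    decision-of-cesarean (DCS) and transducer-removal (RCT) anchored variants.
    Ships the five-tier level rule table as editable data, diagnostic-accuracy
    evaluation (ROC curves with DeLong confidence intervals, Youden-index
    cutoff selection, Fisher exact and rank/parametric group comparisons,
    Hanley-McNeil AUC sample-size calculation, cohort summary tables), and a
    seeded synthetic labor-cohort generator whose deceleration burden drives a
    respiratory-then-metabolic acidosis mechanism, so the full scoring and
    evaluation pipeline can be exercised end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
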