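Package: kidsms
Title: Kid-Short Marfan Score and Revised Ghent Criteria for Pediatric
    Marfan Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule engines for the Kid-Short Marfan Score (Kid-SMS), a
    pediatric pre-test probability stratifier for Marfan syndrome, and for
    the revised Ghent (Ghent-2) diagnostic criteria, together with the
    machinery needed to evaluate a diagnostic score against a reference
    standard: fourfold tables, exact (Clopper-Pearson) binomial confidence
    intervals, positive likelihood ratio, Fisher's exact test, and
    Kaplan-Meier / log-rank comparison of age at risk stratification
    versus age at diagnosis.  Includes pluggable echocardiographic Z-score
    nomograms for sinus-of-Valsalva and pulmonary-artery dilatation, a
    CSV cohort data model with strict absent-versus-negative semantics,
    and a deterministic synthetic validation cohort of 106 patients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    jsonlite
Config/testthat/edition: 3
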