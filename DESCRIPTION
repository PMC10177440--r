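Package: umstrat
Title: Risk Stratification Strategies for Uveal Melanoma Liver Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares prognostic systems used to stratify uveal-melanoma
    patients for liver surveillance. Provides a synthetic patient-cohort
    generator calibrated to the statistical structure of a large ocular
    oncology case series, threshold-based stratification strategies
    (continuous metastasis-risk scores with single or chromosome-3-dependent
    dual thresholds, ordinal tumour stage, monosomy 3), diagnostic accuracy
    statistics (sensitivity and specificity with Clopper-Pearson exact
    intervals, predictive values, empirical ROC curves, AUC with DeLong
    intervals, the DeLong paired AUC test with Holm adjustment), and a
    health-economic impact model translating false-positive reductions into
    scan counts and NHS imaging costs.
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
    pROC,
    jsonlite
Config/testthat/edition: 3
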