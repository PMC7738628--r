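Package: hitca
Title: Hypoxia-Ischemia Time-Course Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential-expression calling, kinetics classification,
    regulation-index (R-Index) scoring, cross-age response-core extraction,
    developmental-interference classification and gene-set over-representation
    analysis for two-color microarray time courses of the neonatal mouse brain
    response to hypoxia-ischemia, together with a synthetic-data generator that
    plants known regulations so every stage of the pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
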