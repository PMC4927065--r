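Package: twinmetab
Title: Twin-Cohort Nutritional Metabolomics Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and replication of food-group to blood-metabolite
    associations in twin cohorts using the co-twin control design. Implements
    preprocessing of non-targeted (run-day median normalisation, missingness
    filtering, run-day minimum imputation, rank-based inverse normal
    transformation) and targeted (log transform, cross-platform overlap
    removal) metabolite panels, conversion of food-frequency questionnaire
    items into energy-adjusted food-group intakes by the residual method,
    family random-intercept regression scans partitioned by monozygotic-pair
    discordance, inverse-variance fixed-effect meta-analysis, and an additive
    genotype to food-intake follow-up scan. Includes a synthetic twin-cohort
    generator with planted effects and known variance components so the whole
    pipeline is testable without access-restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
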