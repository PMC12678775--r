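Package: metadiet
Title: Diet, Faecal Metabolome and Gut Microbiome Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis pipeline linking habitual diet measured by food
    frequency questionnaires (FFQ) to the faecal metabolome and gut microbiome
    composition in twin cohorts. Implements FFQ quality control and
    energy adjustment, a priori dietary index scoring (PDI/hPDI/uPDI, DASH,
    aMED, plant and meat percentages) and pooled-cohort-equation 10-year ASCVD
    risk; metabolite run-day normalisation, minimum-value imputation and
    inverse normal transformation; compositional microbiome transforms and
    diversity metrics; twin-aware random-forest prediction with Boruta feature
    selection and mean-masking recursive feature elimination; fast
    restricted-maximum-likelihood mixed-model association scans with
    effective-number-of-tests Bonferroni correction and fixed-effects
    meta-analysis; PERMANOVA, pathway overrepresentation and signed-profile
    clustering; and a causal mediation screen for diet-microbe-metabolite
    trios. Ships a synthetic twin-cohort generator with a machine-readable
    registry of planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    MASS,
    cluster,
    jsonlite,
    lme4,
    ranger,
    vegan
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    metafor,
    lmerTest,
    withr
Config/testthat/edition: 3
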