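Package: morbclust
Title: Multimorbidity Pattern Discovery by Yule's Q and Ward Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies multimorbidity patterns in survey cohorts by
    agglomerative hierarchical clustering of chronic conditions. Hypertension
    status is derived from measured blood pressure and self-report under a
    configurable diagnostic criterion (140/90 or 130/80 mmHg thresholds ship
    as built-ins), pairwise disease association is measured by Yule's Q, and
    diseases are clustered with Ward's method on the 1 - Q dissimilarity.
    Includes stratified prevalence tabulation, cardiometabolic-pattern
    analytics (combination frequencies, component shares), subgroup
    replication with cluster-stability summaries, and a latent-threshold
    synthetic cohort generator with planted block structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
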