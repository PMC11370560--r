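Package: sipflow
Title: Home-Cage Polysubstance Drinking Analysis for RFID Lickometer Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for group-housed home-cage drinking
    experiments in which RFID-gated drinking stations record per-animal
    visits (high-frequency antenna reads) and volumetric drinking monitors
    record fluid consumption. Integrates the two acquisition streams into
    animal-attributed visit bouts and drink events; computes body-weight
    normalized intake by day, light/dark phase and zeitgeber time;
    two-bottle-choice substance and dose preference indices; a 60-minute
    window polysubstance co-use classification with chi-squared
    comparisons of combination distributions; PCA plus k-means behavioral
    phenotyping with a bootstrap cluster-stability evaluation
    (homogeneity, completeness, V-measure, adjusted Rand, adjusted mutual
    information); and the mixed-design repeated-measures ANOVA battery
    used to compare sexes and phenotype clusters. A seeded synthetic-data
    generator emulates the full acquisition system so every stage is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
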