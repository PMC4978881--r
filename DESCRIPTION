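Package: sporeffect
Title: Sporulation Efficiency Phenotyping and Discovery of Allele-Specific
    Mediator Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies yeast sporulation efficiency differences between
    strains with quasi-binomial generalized linear model tests (pair and
    allele-by-deletion interaction tests), models meiotic progression from
    nuclei-count time courses with delayed first-order kinetics and
    bootstrap uncertainty, detects temporal differential expression between
    two strains with a spline F-statistic, permutation null and Storey
    q-values, clusters differential genes into qualitative temporal trend
    classes, tests transcription-factor regulons for over-representation in
    trend clusters, and classifies candidate genes as causal mediators,
    allele-independent effectors or non-effectors from allele-by-deletion
    sporulation count designs. Includes a synthetic-data generator that
    emulates all pipeline inputs with planted truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
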