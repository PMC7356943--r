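Package: microgrs
Title: Gene-Microbiome Interaction Analysis for Adiposity with Data-Driven
    Genetic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how host genetics and the gut microbiome
    jointly associate with adiposity. Implements a data-driven genetic risk
    score (GRS) built from per-SNP nonparametric genotype/BMI tests with
    post-hoc risk coding, family-level 16S microbiome statistics (cumulative
    sum scaling normalization, Shannon/Chao1/Bray-Curtis diversity,
    LDA-effect-size biomarker scoring, zero-inflated Gaussian differential
    abundance, random-forest importance ranking with ROC validation), and
    sex-stratified GRS-by-taxon interaction regressions with predicted BMI
    curves. A synthetic cohort generator emulating the statistical structure
    of a mixed-weight adult cohort makes the full pipeline testable without
    access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
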