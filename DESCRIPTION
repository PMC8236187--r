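Package: devclock
Title: Development-Stage Epigenetic Clocks for Prenatal Brain and Stem-Cell Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and applying epigenetic age clocks on the
    prenatal (days post-conception) timescale. Covers quality control and
    probe-type-aware quantile normalization of Illumina 450K/EPIC beta and
    intensity matrices, harmonization of heterogeneous age encodings to days
    post-conception, elastic-net training of methylation clocks with
    cross-validated shrinkage selection, application of arbitrary published
    clock coefficient sets (including age-transformed clocks), accuracy
    evaluation with sex-interaction sensitivity analyses, and the
    cell-stage comparison statistics (t-tests, ANOVA with Tukey HSD,
    random-intercept mixed models) used to profile iPSC/NPC/neuron models.
    Includes a synthetic methylation data generator so the full workflow is
    testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    lme4,
    limma,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
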