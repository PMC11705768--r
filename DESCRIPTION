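Package: tumorspec
Title: Bayesian Tumor-Specificity Scoring of Therapeutic Targets from
    Multimodal Normal-Tissue Evidence
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers a continuous tumor-specificity score sigma in (0,1) for
    each candidate therapeutic target (gene, splice junction, or other
    druggable entity) by jointly modeling three lines of healthy-tissue
    evidence under a hierarchical Bayesian model fitted with stochastic
    variational inference: per-tissue RNA detection fractions (Poisson
    channel), normalized RNA counts (LogNormal channel), and
    immunohistochemistry staining labels (Categorical channel).  Supports
    tunable per-tissue importance weights, an optional tumor-versus-normal
    log-fold-change channel, logic-AND combinatorial target-pair scoring,
    precision-recall benchmarking, prior and posterior predictive checks,
    and a generative simulator for fully synthetic test datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
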