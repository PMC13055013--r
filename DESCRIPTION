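Package: hemimorph
Title: Preserved-Hemisphere Morphometry Analysis for Pediatric Epilepsy
    Surgery Cohorts
Version: 0.1.0
Authors@R:
    person("Morphometry", "Maintainers", email = "maintainers@hemimorph.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for comparing regional brain morphometry
    (FreeSurfer-style cortical thickness, surface area and volume, subcortical
    and gross hemisphere volumes) between post-surgical pediatric epilepsy
    patients and controls. Implements measure-specific normalization,
    empirical-Bayes scanner harmonization with additive and multiplicative
    batch effects, stratified winsorization, permutation-null general linear
    models with Benjamini-Hochberg correction and BIC Bayes factors, forward
    binary logistic regression with Nagelkerke R-squared effect-size bands,
    cohort matching statistics, a cross-measure correlation screen, and a
    synthetic cohort generator that emulates the assumed data structure so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
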