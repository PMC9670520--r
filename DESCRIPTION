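Package: bdvoi
Title: Case-Exclusive Recurrent Variant Discovery and Cancer-Risk Labeling
    in Birth-Defect Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies germline "variants of interest" associated with
    malignant tumors in patients with non-chromosomal birth defects (BD)
    from multi-sample whole-genome genotypes: variants recurrent in at
    least three unrelated BD+cancer probands and absent from BD-only
    probands and healthy family controls. Selected variants are stratified
    by genomic region (coding, non-coding, intergenic), collapsed to
    gene-level mutation-load features, reduced by random-forest importance
    and greedy forward feature selection, and used to train per-stratum
    multilayer-perceptron classifiers whose labels are combined by
    majority vote. Includes hypergeometric gene-set enrichment, exact-key
    overlap against a somatic-variant catalogue, a mutation-load group
    comparison, and a synthetic-cohort simulator with planted signal and
    family structure so the whole pipeline is testable without restricted
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ranger,
    vcfR,
    rtracklayer,
    IRanges,
    S4Vectors,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
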