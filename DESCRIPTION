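Package: mitotriage
Title: Phenotype-Driven Prioritization of Mitochondrial DNA Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genotype- and phenotype-side triage of mitochondrial DNA (mtDNA)
    variants in large rare-disease cohorts. Applies sample-level quality gates
    and a four-criterion variant prioritization cascade (heteroplasmy floor,
    curated disease-association status, population allele frequency) with
    haplogroup-marker exclusion; scores each patient's Human Phenotype
    Ontology (HPO) profile against a reference table of published mtDNA
    disease probands using Lin's information-content-based semantic
    similarity; calibrates score thresholds by ROC analysis with DeLong
    confidence intervals and Youden's index; and classifies candidates into
    low/medium/high phenotype-similarity tiers with recommended actions.
    Ships a synthetic cohort generator (ontology, reference profiles, noisy
    patient phenotypes, spiked variant tables) so the full pipeline is
    testable end to end without access to clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
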