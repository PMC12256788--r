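#!/usr/bin/env Rscript
# Simulate the study cohort: a phenotype test cohort of 47 mtDNA-disease
# patients (noisy copies of reference proband profiles, each carrying one
# spiked causal mtDNA variant) against 1,460 nuclear-diagnosis patients
# (122 nuclear-mitochondrial, 1,338 nuclear-other), with haplogroup
# markers, benign background variants, and ~10% of samples failing mtDNA
# QC. All downstream steps read the TSVs written here.

library(mitotriage)

seed <- 101
out_dir <- "results/cohort"

spec <- cohort_spec(seed = seed)
cohort <- generate_cohort(spec)
write_cohort(cohort, out_dir)

cat("cohort written to", out_dir, "\n")
print(cohort)
cat("\ngroup sizes:\n")
print(table(cohort$truth$group))
cat("\nsamples failing QC:", sum(cohort$truth$qc_fail),
    sprintf("(%.1f%%)\n", 100 * mean(cohort$truth$qc_fail)))
cat("variant calls:", nrow(cohort$variants),
    "| spiked causal variants:", sum(!is.na(cohort$truth$causal_variant)), "\n")
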