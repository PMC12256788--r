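#!/usr/bin/env Rscript
# Genotype-side triage: sample QC (>= 50% of the mtDNA assembled, >= 5x
# mean depth), exclusion of the sample's own haplogroup-defining markers,
# and the four-criterion prioritization (heteroplasmy >= 1% AND confirmed
# status, MitoPhen membership, or reported status with AF < 0.2%).

library(mitotriage)

in_dir <- "results/cohort"
out_dir <- "results/filter"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

qc <- read.delim(file.path(in_dir, "qc.tsv"))
variants <- read_variants_tsv(file.path(in_dir, "variants.tsv"))
annotation <- read.delim(file.path(in_dir, "annotation.tsv"))
markers <- read.delim(file.path(in_dir, "markers.tsv"))

filt <- filter_cohort(qc, variants, annotation, markers)

write.table(filt$candidates, file.path(out_dir, "prioritized_variants.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(as.list(filt$funnel), file.path(out_dir, "funnel.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat("variant funnel:\n")
for (nm in names(filt$funnel)) cat(sprintf("  %-12s %d\n", nm, filt$funnel[[nm]]))
cat("\nprioritization criteria among survivors:\n")
print(table(filt$candidates$criterion))
cat("\ntruth check: ")
truth <- read.delim(file.path(in_dir, "truth.tsv"))
cases <- truth[truth$is_mtdna_case & !truth$qc_fail, ]
hit <- paste(cases$sample_id, cases$causal_variant) %in%
  paste(filt$candidates$sample_id, filt$candidates$variant)
cat(sum(hit), "of", nrow(cases), "QC-passing causal variants recovered\n")
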