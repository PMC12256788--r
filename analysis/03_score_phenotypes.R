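#!/usr/bin/env Rscript
# Phenotype-side scoring: information content from the reference proband
# corpus, then each patient's HPO profile scored against every reference
# profile by Lin's semantic similarity (symmetric best-match average; the
# patient's score is the maximum over references).

library(mitotriage)

in_dir <- "results/cohort"
out <- "results/scores.tsv"

ont <- fixture_ontology()
refs <- read_reference_tsv(file.path(in_dir, "references.tsv"))
patients <- read_profiles_tsv(file.path(in_dir, "patients.tsv"))
truth <- read.delim(file.path(in_dir, "truth.tsv"))

ic <- compute_ic(ont, refs$profiles)
scores <- score_cohort(ic, ont, patients, refs)
scores$group <- truth$group[match(scores$subject_id, truth$sample_id)]
scores$score <- round(scores$score, 6)
scores$mean_ic <- round(scores$mean_ic, 6)

write.table(scores, out, sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n\nscore distribution by diagnosis group:\n")
print(do.call(rbind, tapply(scores$score, scores$group, summary)))
cat("\nmedian non-redundant HPO terms per person:",
    stats::median(scores$n_terms), "\n")
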