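#!/usr/bin/env Rscript
# Threshold calibration on the labeled cohort: ROC with DeLong 95% CI,
# Youden's optimal cut-off, operating points at the 0.3 / 0.48 / 0.5
# thresholds, and the three-group Kruskal-Wallis + Dunn comparison.

library(mitotriage)

scores <- read.delim("results/scores.tsv")
out_json <- "results/calibration.json"
out_roc <- "results/roc_curve.tsv"

cal <- calibrate_thresholds(scores)

roc_tab <- data.frame(
  threshold = cal$roc$thresholds, sens = cal$roc$sens, spec = cal$roc$spec
)
write.table(roc_tab, out_roc, sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(
    auc = cal$auc, auc_ci = cal$auc_ci,
    youden = cal$youden, at_thresholds = cal$at_thresholds,
    kruskal_wallis = list(h = cal$groups$kw_h, p = cal$groups$kw_p),
    dunn = cal$groups$pairwise
  ),
  out_json, auto_unbox = TRUE, pretty = TRUE, digits = NA
)

cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f)\n", cal$auc, cal$auc_ci[1], cal$auc_ci[2]))
cat(sprintf("Youden optimum: threshold %.3f, sensitivity %.0f%%, specificity %.0f%%\n",
            cal$youden$threshold, 100 * cal$youden$sens, 100 * cal$youden$spec))
cat("\noperating points:\n")
print(transform(cal$at_thresholds, sens = round(100 * sens), spec = round(100 * spec)))
cat("\ngroup comparison (Kruskal-Wallis + Dunn, Bonferroni):\n")
print(cal$groups)
cat("\nwrote", out_json, "and", out_roc, "\n")
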