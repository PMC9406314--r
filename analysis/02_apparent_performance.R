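#!/usr/bin/env Rscript
# Apparent (resubstitution) performance of both classifiers on the cohort
# written by 01_simulate_cohort.R: pairwise sensitivity/specificity for
# MT versus benign, MT versus PA and MT versus WT.

suppressPackageStartupMessages(library(adchist))

cohort <- if (file.exists("scratch/cohort/manifest.json")) {
  read_cohort_manifest("scratch/cohort/manifest.json")
} else {
  generate_cohort(cohort_generator_config(seed = 924L))
}
ch <- cohort_histograms(cohort)

rows <- list()
for (method in c("histogram", "mean")) {
  rep <- apparent_metrics(ch, method, alpha = 0.5)
  write_report(rep, sprintf("results/apparent_%s.json", method))
  for (cmp in names(rep$pairwise_sens_spec)) {
    ss <- rep$pairwise_sens_spec[[cmp]]
    rows[[length(rows) + 1]] <- data.frame(
      comparison = cmp, method = method,
      sensitivity_pct = round(100 * ss[["sensitivity"]], 1),
      specificity_pct = round(100 * ss[["specificity"]], 1))
  }
  cat(sprintf("%s method: apparent total accuracy %.1f%%\n",
              method, 100 * rep$total_accuracy))
}
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
write.csv(tab, "results/apparent_pairwise.csv", row.names = FALSE)

cat("\nOn this well-separated synthetic cohort both methods are perfect at\n")
cat("resubstitution; differences between them only surface once class\n")
cat("distributions overlap (see 04_overlap_stress.R).\n")
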