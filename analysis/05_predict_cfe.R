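#!/usr/bin/env Rscript
# Predictive carry-forward analysis: correctness prediction per phase with
# the validation-weighted seven-member ensemble under
# leave-one-participant-out cross-validation, permutation feature
# importance, dense ranks and the rank-based CFE classes. The heavy step.

source("analysis/00_config.R")
library(data.table)

cohort <- read_cohort(SESSION_DIR)
res <- run_cfe_pipeline(cohort, demo_run_config(), include_predictive = TRUE)
write_reports(res$report_tables, RESULTS_DIR)

if (!is.null(res$report_tables$metrics)) {
  cat("holdout prediction metrics per domain and phase:\n")
  print(res$report_tables$metrics)
  cat("\nmajority baseline on the same label imbalance:\n")
  labs <- res$measurements[
    , .(label = label[1]), by = .(participant, domain, question)
  ]$label
  mb <- majority_baseline_metrics(labs)
  cat(sprintf(
    "  precision %.3f, recall %.3f, F1 %.3f\n", mb$precision, mb$recall, mb$f1
  ))
}
if (!is.null(res$report_tables$ranks)) {
  cat("\nfeatures in any phase top set, with ranks and CFE class:\n")
  print(res$report_tables$ranks)
}
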