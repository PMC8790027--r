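#!/usr/bin/env Rscript
# Preprocess the raw streams (I-VT gaze events, pupil z-scores, EDA
# tonic/phasic decomposition, leading-baseline normalization), window them
# (10 s windows, 5 s hop) and extract the window measurements and the
# per-(question, phase) feature vectors.

source("analysis/00_config.R")
library(data.table)

cohort <- read_cohort(SESSION_DIR)
rc <- demo_run_config()

res <- run_cfe_pipeline(cohort, rc, include_predictive = FALSE)
meas <- res$measurements
fwrite(meas, file.path(RESULTS_DIR, "measurements.tsv"), sep = "\t")

md <- copy(meas)[, value := norm_value]
feats <- feature_table(md)
fwrite(feats, file.path(RESULTS_DIR, "features.tsv"), sep = "\t")

cat(sprintf(
  "%d window-level measurement values over %d windows; %d feature rows x %d columns\n",
  sum(is.finite(meas$value)), length(unique(meas$window)) ,
  nrow(feats), ncol(feats) - 5
))
cat("measurement availability by phase (share of non-missing):\n")
print(dcast(
  meas[!is.na(window), .(avail = mean(is.finite(value))),
    by = .(measurement, phase)
  ],
  measurement ~ phase, value.var = "avail"
))
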