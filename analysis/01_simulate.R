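#!/usr/bin/env Rscript
# Simulate a cohort of multimodal game sessions and write them to disk in
# the on-disk session formats (gaze CSV, Empatica-style EDA/HR CSVs,
# skeleton CSV, game-log JSON).
#
# Two effects are planted: a decreasing wrong-affinity mean-HR effect
# (0.9 / 0.6 / 0.35 SD units across See-Solve / Move / Respond) and a
# See-Solve-concentrated cognitive-load effect. Everything downstream
# should rediscover exactly these.

source("analysis/00_config.R")

cohort <- generate_cohort(demo_config(), demo_effects())
write_cohort(cohort, SESSION_DIR)

truth <- data.table::rbindlist(
  lapply(cohort, function(b) b$ground_truth$cycles)
)
cat(sprintf(
  "wrote %d sessions (%d question cycles, %.0f%% answered right) to %s\n",
  length(cohort), nrow(truth) / 3,
  100 * mean(truth$label == "right"), SESSION_DIR
))
data.table::fwrite(
  truth, file.path(RESULTS_DIR, "ground_truth_cycles.tsv"), sep = "\t"
)
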