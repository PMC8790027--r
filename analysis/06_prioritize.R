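#!/usr/bin/env Rscript
# Turn the classified carry-forward effects into the ordered feedback plan:
# Perfect before Pseudo before None, then See-Solve effect size, with the
# no-CFE measurements ordered by their significance pattern first.

source("analysis/00_config.R")
library(data.table)

cohort <- read_cohort(SESSION_DIR)
res <- run_cfe_pipeline(cohort, demo_run_config(), include_predictive = FALSE)

for (d in names(res$plans)) {
  cat("-- feedback plan:", d, "\n")
  print(res$plans[[d]][, .(priority, measurement, cfe_class, feedback)])
}
write_reports(res$report_tables, RESULTS_DIR)
cat(sprintf(
  "\nplan JSON written to %s\n", file.path(RESULTS_DIR, "feedback_plan.json")
))
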