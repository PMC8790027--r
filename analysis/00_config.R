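# Shared settings for the numbered analysis scripts.
#
# The demo cohort is deliberately smaller than the study conditions
# (12 participants instead of 40) so every script runs in seconds; the
# acceptance script and the test suite exercise the full study sizes.

library(carryforward)

ANALYSIS_SEED <- 2024L
N_PARTICIPANTS <- 12L

SESSION_DIR <- "results/sessions"
RESULTS_DIR <- "results"

demo_effects <- function() {
  list(
    # decreasing wrong-affinity heart-rate effect across the S2MR phases
    effect_spec("mean_hr", "wrong", 0.9, 0.6, 0.35),
    # cognitive load elevated for wrong answers only while solving:
    # present in See-Solve, absent later, hence no carry-forward
    effect_spec("cognitive_load", "wrong", 0.8, 0, 0)
  )
}

demo_config <- function() {
  cohort_config(n_participants = N_PARTICIPANTS, seed = ANALYSIS_SEED)
}

demo_run_config <- function() run_config(seed = ANALYSIS_SEED)

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
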