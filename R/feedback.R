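# Feedback mapping and prioritization.
#
# Each measurement maps to an intervention type; measurements whose affinity
# is with the desired (right) outcome get positive reinforcement instead of
# remediation. The plan orders measurements by CFE class (Perfect before
# Pseudo before None), then by See-Solve effect size; measurements without
# CFE are ordered first by their significance pattern across the phases
# (See-Solve before Move before Respond, lexicographically), then by
# See-Solve effect size; the final tie-break puts undesired-outcome affinity
# first.

FEEDBACK_MAP <- c(
  cognitive_load = "worked_example_or_hint",
  saccade_velocity = "content_hint",
  ipi = "gaze_contingent_overlay",
  mean_hr = "pause_suggestion",
  eda_peaks = "emotion_regulation",
  phasic_eda = "emotion_regulation",
  tonic_eda = "emotion_regulation"
)

#' Feedback type for a measurement and its affinity
#'
#' @param measurement one of [supported_measurements()]
#' @param affinity "right" or "wrong" — the label the higher value co-occurs
#'   with; affinity with the desired outcome yields encouragement, not
#'   remediation
#' @return a feedback type string
#' @export
feedback_for <- function(measurement, affinity) {
  if (!measurement %in% names(FEEDBACK_MAP)) {
    stopf("no feedback mapping for measurement '%s'", measurement)
  }
  stopifnot(affinity %in% c("right", "wrong"))
  if (affinity == "right") {
    return("encouragement")
  }
  unname(FEEDBACK_MAP[[measurement]])
}

# sortable key per measurement; smaller sorts earlier (= higher priority)
feedback_sort_key <- function(cfe_class, es_ss, sig_ss, sig_move,
                              sig_respond, affinity) {
  class_ord <- match(cfe_class, c("perfect", "pseudo", "none"))
  # significance pattern scored lexicographically, See-Solve most significant
  sig_score <- 4 * isTRUE(sig_ss) + 2 * isTRUE(sig_move) +
    1 * isTRUE(sig_respond)
  list(
    class_ord = class_ord,
    sig_rank = if (class_ord == 3) -sig_score else 0,
    es_rank = -ifelse(is.finite(es_ss), es_ss, -Inf),
    affinity_rank = ifelse(affinity == "wrong", 0, 1)
  )
}

#' Build the prioritized feedback plan of one domain
#'
#' @param cfe data.table from [cfe_inferential_table()]
#' @param effects data.table from [phase_effect_table()]
#' @return data.table plan: `priority` (1 = first), `measurement`,
#'   `cfe_class`, `affinity`, `feedback`, `rationale`
#' @export
prioritize <- function(cfe, effects) {
  if (nrow(cfe) == 0) {
    return(data.table(
      priority = integer(0), measurement = character(0),
      cfe_class = character(0), affinity = character(0),
      feedback = character(0), rationale = character(0)
    ))
  }
  rows <- lapply(seq_len(nrow(cfe)), function(i) {
    m <- cfe$measurement[i]
    e <- effects[measurement == m]
    ss <- e[phase == "see_solve"]
    aff <- ss$affinity
    if (is.na(aff)) aff <- "wrong"
    key <- feedback_sort_key(
      cfe$cfe_class[i], ss$effect_size,
      e[phase == "see_solve"]$significant,
      e[phase == "move"]$significant,
      e[phase == "respond"]$significant,
      aff
    )
    data.table(
      measurement = m, cfe_class = cfe$cfe_class[i], affinity = aff,
      es_see_solve = ss$effect_size,
      class_ord = key$class_ord, sig_rank = key$sig_rank,
      es_rank = key$es_rank, affinity_rank = key$affinity_rank
    )
  })
  plan <- rbindlist(rows)
  setorder(plan, class_ord, sig_rank, es_rank, affinity_rank, measurement)
  plan[, priority := seq_len(.N)]
  plan[, feedback := mapply(feedback_for, measurement, affinity)]
  plan[, rationale := sprintf(
    "%s CFE; see-solve effect size %.3f; affinity with %s answers",
    cfe_class, es_see_solve, affinity
  )]
  plan[, .(priority, measurement, cfe_class, affinity, feedback, rationale)]
}
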