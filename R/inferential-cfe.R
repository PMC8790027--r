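# Inferential carry-forward analysis: per (measurement, phase) tests of the
# right/wrong difference, Bonferroni-adjusted within a game domain, and the
# four-condition CFE classification.
#
# Test procedure per (measurement, phase): cycle values are first averaged
# to participant-by-label means (the design's unit of analysis: a
# repeated-measures ANOVA over 40 participants has df (1, 39), a Welch test
# fractional dfs just below that). Shapiro-Wilk on the residuals of the
# group model decides a z-transform; a Breusch-Pagan test across groups
# decides between the repeated-measures ANOVA with the participant as
# grouping variable and a Welch one-way ANOVA (which has no
# repeated-measures form). Computing both paths on the same
# participant-level means keeps the partial eta-squared effect sizes
# commensurable across phases, which the carry-forward ordering conditions
# compare. Affinity is the label of the group with the larger mean.

#' Bonferroni adjustment
#'
#' @param p raw p values of one test family
#' @param m family size (defaults to `length(p)`)
#' @return adjusted p values, capped at 1
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(length(p) >= 1, m >= 1)
  pmin(1, p * m)
}

#' Group-difference test for one measurement in one phase
#'
#' @param values per-cycle measurement values
#' @param labels per-cycle correctness labels ("right"/"wrong")
#' @param participants per-cycle participant ids
#' @param alpha significance level
#' @return an `effect_result` list: `F`, `df1`, `df2`, `p`, `effect_size`
#'   (partial eta-squared), `affinity`, `welch_used`, `ztransformed`,
#'   `untestable`, `n`
#' @export
run_phase_test <- function(values, labels, participants, alpha = 0.05) {
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]
  labels <- labels[ok]
  participants <- participants[ok]
  res <- list(
    F = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_,
    effect_size = NA_real_, affinity = NA_character_,
    welch_used = FALSE, ztransformed = FALSE, untestable = FALSE,
    n = length(values)
  )
  class(res) <- "effect_result"
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L) ||
    length(unique(participants)) < 2L) {
    res$untestable <- TRUE
    return(res)
  }

  # unit of analysis: participant-by-label means
  agg <- aggregate(
    values, list(pid = participants, g = factor(labels,
      levels = c("right", "wrong")
    )), mean
  )
  v <- agg$x
  g <- agg$g
  if (length(unique(g)) < 2L || any(table(g) < 2L)) {
    res$untestable <- TRUE
    return(res)
  }
  means <- tapply(v, g, mean)
  res$affinity <- names(which.max(means))

  # residual normality -> z-transform
  resid <- v - ave(v, g)
  sw <- if (length(resid) >= 3 && length(resid) <= 5000) {
    shapiro.test(resid)$p.value
  } else {
    1
  }
  if (is.finite(sw) && sw < 0.05 && sd(v) > 0) {
    v <- (v - mean(v)) / sd(v)
    res$ztransformed <- TRUE
  }

  # homoscedasticity across groups
  bp <- tryCatch(
    lmtest::bptest(lm(v ~ g))$p.value,
    error = function(e) 1
  )
  res$effect_size <- partial_eta_squared(v, g)
  if (is.finite(bp) && bp < 0.05) {
    # Welch one-way ANOVA (no repeated-measures form)
    w <- oneway.test(v ~ g, var.equal = FALSE)
    res$F <- unname(w$statistic)
    res$df1 <- unname(w$parameter[1])
    res$df2 <- unname(w$parameter[2])
    res$p <- w$p.value
    res$welch_used <- TRUE
  } else {
    # repeated-measures ANOVA, participant as grouping variable; only
    # participants observed under both labels contribute to the pairing
    both <- names(which(table(agg$pid) == 2L))
    keep <- agg$pid %in% both
    if (sum(keep) >= 4L && length(both) >= 2L) {
      pid <- factor(agg$pid[keep])
      fit <- aov(v[keep] ~ g[keep] + Error(pid))
      within <- summary(fit)[["Error: Within"]]
    } else {
      within <- NULL
    }
    if (is.null(within)) {
      res$untestable <- TRUE
      return(res)
    }
    stab <- within[[1]]
    res$F <- stab[1, "F value"]
    res$df1 <- stab[1, "Df"]
    res$df2 <- stab["Residuals", "Df"]
    res$p <- stab[1, "Pr(>F)"]
  }
  res
}

#' Partial eta-squared from a one-way layout
#'
#' SS_effect / (SS_effect + SS_error).
#'
#' @param values numeric observations
#' @param groups factor of group labels
#' @return effect size in `[0, 1]`
#' @export
partial_eta_squared <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  ng <- tapply(values, groups, length)
  ss_effect <- sum(ng * (gm - grand)^2)
  ss_error <- sum((values - ave(values, groups))^2)
  if (ss_effect + ss_error == 0) return(0)
  ss_effect / (ss_effect + ss_error)
}

#' Run the inferential battery for one game domain
#'
#' Aggregates the normalized window measurements to one value per
#' (participant, question, phase), tests each of the seven measurements in
#' each phase, and applies a Bonferroni correction over the whole
#' measurement-by-phase family of the domain.
#'
#' @param measurements long normalized measurement table of one domain
#' @param alpha significance level
#' @param measurement_set measurements to test
#' @return data.table with one row per (measurement, phase): test statistic,
#'   dfs, raw and adjusted p, effect size, affinity, flags
#' @export
phase_effect_table <- function(measurements, alpha = 0.05,
                               measurement_set = supported_measurements()) {
  cyc <- measurements[
    measurement %in% measurement_set & !is.na(window) & !is.na(phase),
    .(value = mean(value, na.rm = TRUE)),
    by = .(measurement, participant, question, phase, label)
  ]
  cyc <- cyc[is.finite(value)]
  grid <- data.table::CJ(
    measurement = measurement_set,
    phase = c("see_solve", "move", "respond")
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- cyc[measurement == grid$measurement[i] & phase == grid$phase[i]]
    r <- run_phase_test(d$value, d$label, d$participant, alpha)
    data.table(
      measurement = grid$measurement[i], phase = grid$phase[i],
      F = r$F, df1 = r$df1, df2 = r$df2, p = r$p,
      effect_size = r$effect_size, affinity = r$affinity,
      welch_used = r$welch_used, ztransformed = r$ztransformed,
      untestable = r$untestable, n = r$n
    )
  })
  out <- rbindlist(rows)
  m <- sum(!out$untestable)
  out[, p_adj := ifelse(untestable, NA_real_, bonferroni_adjust(p, max(m, 1)))]
  out[, significant := !untestable & !is.na(p_adj) & p_adj < alpha]
  out
}

#' Classify the inferential carry-forward effect of one measurement
#'
#' Four conditions over the three phase results: (1) significant everywhere;
#' (2) the effect size peaks in See-Solve; (3) the Move effect size exceeds
#' the Respond effect size; (4) all affinities agree. Strict inequalities —
#' ties fail. Under the default `"examples"` rule Perfect requires all four
#' and Pseudo is the condition-3 failure with 1, 2 and 4 holding; under
#' `"text"` Pseudo is instead the condition-4 failure with 1-3 holding.
#'
#' @param effects data.table of the measurement's three phase rows
#'   (`phase`, `effect_size`, `significant`, `affinity`, `untestable`)
#' @param pseudo_rule `"examples"` or `"text"`
#' @return `cfe_result` list: `cfe_class`, the four condition booleans, and
#'   `reason` for untestable input
#' @export
classify_cfe_inferential <- function(effects,
                                     pseudo_rule = c("examples", "text")) {
  pseudo_rule <- match.arg(pseudo_rule)
  need <- c("see_solve", "move", "respond")
  stopifnot(all(need %in% effects$phase))
  e <- effects[match(need, effects$phase)]
  res <- list(
    cfe_class = "none",
    sig_all = FALSE, max_in_see_solve = FALSE, move_gt_respond = FALSE,
    affinity_consistent = FALSE, reason = NA_character_
  )
  class(res) <- "cfe_result"
  if (any(e$untestable)) {
    res$reason <- "untestable phase"
    return(res)
  }
  es <- e$effect_size
  res$sig_all <- all(e$significant)
  res$max_in_see_solve <- es[1] > es[2] && es[1] > es[3]
  res$move_gt_respond <- es[2] > es[3]
  res$affinity_consistent <- length(unique(e$affinity)) == 1L
  res$cfe_class <- cfe_class_from_conditions(
    res$sig_all, res$max_in_see_solve, res$move_gt_respond,
    res$affinity_consistent, pseudo_rule
  )
  res
}

# total decision rule over the four condition booleans
cfe_class_from_conditions <- function(sig_all, max_in_see_solve,
                                      move_gt_respond, affinity_consistent,
                                      pseudo_rule = "examples") {
  if (sig_all && max_in_see_solve && move_gt_respond && affinity_consistent) {
    return("perfect")
  }
  if (pseudo_rule == "examples") {
    if (sig_all && max_in_see_solve && affinity_consistent &&
      !move_gt_respond) {
      return("pseudo")
    }
  } else {
    if (sig_all && max_in_see_solve && move_gt_respond &&
      !affinity_consistent) {
      return("pseudo")
    }
  }
  "none"
}

#' Inferential CFE classification for every measurement of a domain
#'
#' @param effect_table output of [phase_effect_table()]
#' @param pseudo_rule see [classify_cfe_inferential()]
#' @return data.table: one row per measurement with the CFE class and the
#'   condition booleans
#' @export
cfe_inferential_table <- function(effect_table,
                                  pseudo_rule = c("examples", "text")) {
  pseudo_rule <- match.arg(pseudo_rule)
  rows <- lapply(unique(effect_table$measurement), function(m) {
    r <- classify_cfe_inferential(effect_table[measurement == m], pseudo_rule)
    data.table(
      measurement = m, cfe_class = r$cfe_class, sig_all = r$sig_all,
      max_in_see_solve = r$max_in_see_solve,
      move_gt_respond = r$move_gt_respond,
      affinity_consistent = r$affinity_consistent
    )
  })
  rbindlist(rows)
}
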