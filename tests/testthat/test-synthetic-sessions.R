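# Synthetic session generator: determinism, study-condition defaults,
# planted effects and their absence under the null.

test_that("configuration and effect specs validate their inputs", {
  expect_error(cohort_config(p_correct = 0), "p_correct")
  expect_error(cohort_config(n_participants = 0))
  expect_error(effect_spec("not_a_measurement", "wrong", 1), "unknown")
  expect_error(effect_spec("mean_hr", "sideways", 1), "affinity")
  cfg <- cohort_config()
  expect_equal(cfg$n_participants, 40L)
  expect_equal(cfg$n_games_per_domain, 3L)
  expect_equal(cfg$n_questions_per_game, 5L)
  expect_equal(cfg$p_correct, 5 / 6)
  expect_length(cfg$domains, 2L)
})

test_that("same seed reproduces bundles exactly", {
  cfg <- cohort_config(n_participants = 2, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # and a different seed does not
  c <- generate_cohort(cohort_config(n_participants = 2, seed = 78))
  expect_false(identical(a[[1]]$gaze, c[[1]]$gaze))
})

test_that("cohort layout matches the configured session structure", {
  cfg <- cohort_config(n_participants = 3, seed = 5)
  coh <- generate_cohort(cfg)
  expect_length(coh, 3L)
  for (b in coh) {
    expect_equal(nrow(b$log), 2 * 3 * 5) # domains x games x questions
    expect_equal(sort(unique(b$log$domain)), c("arithmetic", "literacy"))
    # event order within each question
    expect_true(all(b$log$onset < b$log$selection))
    expect_true(all(b$log$selection < b$log$response))
    # strictly increasing stream timestamps
    expect_true(all(diff(b$gaze$t) > 0))
    expect_true(all(diff(b$eda$t) > 0))
    expect_true(all(diff(b$hr$t) > 0))
    expect_true(all(diff(b$skeleton$t) > 0))
    # ground-truth boundaries inside the cycle
    tr <- b$ground_truth$cycles
    expect_true(all(tr$t_start < tr$t_end))
  }
})

test_that("stream lengths equal duration times sampling rate", {
  b <- generate_session(cohort_config(n_participants = 1, seed = 3),
    participant_id = "p01", seed = 13
  )
  span <- max(b$gaze$t)
  expect_lte(abs(nrow(b$eda) - (span * 64 + 1)), 1)
  expect_lte(abs(nrow(b$hr) - (span * 1 + 1)), 1)
  expect_lte(abs(nrow(b$skeleton) - (span + 1)), 1)
  expect_lte(abs(nrow(b$gaze) - (span * 50 + 1)), 1)
})

test_that("correctness labels follow the configured probability", {
  coh <- cached_cohort("null16", function() {
    generate_cohort(cohort_config(n_participants = 16, seed = 41))
  })
  labels <- unlist(lapply(coh, function(b) b$log$correct))
  n <- length(labels)
  p_hat <- mean(labels)
  # binomial tolerance around 5/6 (~4 sigma)
  expect_lt(abs(p_hat - 5 / 6), 4 * sqrt((5 / 6) * (1 / 6) / n))
  # forcing correctness yields a constant label column
  b <- generate_session(
    cohort_config(n_participants = 1, p_correct = 1 - 1e-12, seed = 1),
    participant_id = "p01", seed = 5
  )
  expect_true(all(b$log$correct))
})

cohens_d_by_label <- function(x, lab) {
  ok <- is.finite(x)
  x <- x[ok]
  lab <- lab[ok]
  x1 <- x[lab == "wrong"]
  x0 <- x[lab == "right"]
  sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x0) - 1) * var(x0)) /
    (length(x1) + length(x0) - 2))
  (mean(x1) - mean(x0)) / sp
}

test_that("null cohorts carry no spurious channel effects", {
  # direct two-sample d on the generated channel phase means, several seeds
  seeds <- 1:8
  dmat <- sapply(seeds, function(s) {
    coh <- generate_cohort(cohort_config(n_participants = 20, seed = 900 + s))
    tr <- rbindlist(lapply(coh, function(b) b$ground_truth$cycles))
    unlist(lapply(split(tr, tr$phase), function(p) {
      c(
        hr = cohens_d_by_label(p$hr_mean, p$label),
        pupil = cohens_d_by_label(p$pupil_mean, p$label),
        scr = cohens_d_by_label(p$scr_count, p$label)
      )
    }))
  })
  # per channel-phase cell the seed-averaged d is near zero, and most
  # individual estimates are small
  expect_true(all(abs(rowMeans(dmat)) < 0.12))
  expect_gt(mean(abs(dmat) < 0.25), 0.8)
})

test_that("planted HR effects shift the raw channel in the stated direction", {
  eff <- list(effect_spec("mean_hr", "wrong", 1.0, 0.7, 0.4))
  coh <- cached_cohort("hr_planted", function() {
    generate_cohort(cohort_config(n_participants = 40, seed = 301), eff)
  })
  tr <- rbindlist(lapply(coh, function(b) b$ground_truth$cycles))
  gaps <- tr[is.finite(hr_mean), .(
    gap = mean(hr_mean[label == "wrong"]) - mean(hr_mean[label == "right"])
  ), by = phase]
  expect_true(all(gaps$gap > 0))
  expect_equal(
    gaps$phase[which.max(gaps$gap)], "see_solve"
  )
  # recovered d close to the planted values
  dd <- tr[, .(d = cohens_d_by_label(hr_mean, label)), by = phase]
  planted <- c(see_solve = 1.0, move = 0.7, respond = 0.4)
  expect_true(all(abs(dd$d - planted[dd$phase]) < 0.25))
})

test_that("a planted HR effect does not leak into other channels", {
  coh <- cached_cohort("hr_planted", function() {
    generate_cohort(
      cohort_config(n_participants = 40, seed = 301),
      list(effect_spec("mean_hr", "wrong", 1.0, 0.7, 0.4))
    )
  })
  tr <- rbindlist(lapply(coh, function(b) b$ground_truth$cycles))
  d_pupil <- abs(tr[, cohens_d_by_label(pupil_mean, label)])
  d_scr <- abs(tr[, cohens_d_by_label(scr_count, label)])
  expect_lt(d_pupil, 0.2)
  expect_lt(d_scr, 0.2)
})

test_that("a single generated cycle carries its planted markers", {
  set.seed(10)
  profile <- participant_profile()
  cyc <- generate_question_cycle(profile, "right", seed = 33)
  expect_equal(nrow(cyc$truth), 3L)
  expect_identical(cyc$truth$phase, c("see_solve", "move", "respond"))
  # respond bounds come straight from the log
  expect_equal(cyc$truth$t_start[3], cyc$log_entry$selection)
  expect_equal(cyc$truth$t_end[3], cyc$log_entry$response)
  # the first question-AOI fixation is at the see-solve onset
  ev <- detect_gaze_events(cyc$gaze, 1.0)
  fix <- ev[kind == "fixation" & t_start >= cyc$log_entry$onset]
  in_q <- carryforward:::point_in_rect(fix$x, fix$y, cyc$layout$question)
  expect_true(any(in_q))
  expect_lt(
    abs(fix$t_start[which(in_q)[1]] - cyc$truth$t_start[1]), 0.021
  )
})
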