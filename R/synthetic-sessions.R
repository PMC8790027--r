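# Synthetic multimodal session generator.
#
# Emulates one study cohort: each participant plays two game domains
# (arithmetic, literacy) of 3 games x 5 multiple-choice questions while
# wearing eye-tracking glasses (gaze + pupil, 50 Hz), a wristband
# (EDA 64 Hz, HR 1 Hz) and standing in front of a skeletal motion sensor
# (25 joints, 1 Hz). Every question cycle carries known ground-truth
# See-Solve / Move / Respond boundaries and, optionally, planted per-phase
# group differences (Cohen's-d scale) between right- and wrong-answered
# cycles on the raw channel each measurement summarizes.

GAZE_DT <- 0.02 # 50 Hz sample spacing, all event durations grid-aligned

# Measurements that accept planted effects (the seven study measurements).
#' Names of the seven supported measurements
#' @return character vector of measurement names
#' @export
supported_measurements <- function() {
  c(
    "cognitive_load", "ipi", "saccade_velocity", "mean_hr",
    "eda_peaks", "phasic_eda", "tonic_eda"
  )
}

# Reference SDs of the raw per-cycle phase means under the null generator,
# frozen from a one-off Monte-Carlo calibration of the default profile
# distributions. A planted effect of size d shifts the affinity group's raw
# channel by d * ref_sd, so a two-sample Cohen's d computed directly on the
# generated channel phase means recovers d.
CF_REF_SD <- c(
  mean_hr = 8.0,        # bpm; dominated by between-participant baseline SD
  cognitive_load = 0.37, # mm pupil diameter
  tonic_eda = 0.78,     # uS tonic level
  phasic_eda = 0.010,   # uS phase-mean phasic level
  eda_peaks = 0.75      # SCR events per phase (rate-driven)
)

# First-order calibration coefficients for the channels where the effect is
# planted through a generative knob rather than an additive level shift
# (bump amplitudes, SCR rate, saccade geometry); these realize an
# approximately d-sized shift of the corresponding phase-mean channel.
CF_EFFECT_COEF <- c(
  phasic_mult = 3.0,   # bump-amplitude multiplier per unit d
  peaks_mult = 1.4,    # SCR rate multiplier per unit d
  ipi_logit = 0.80,    # logit shift of between-AOI transition probability
  ipi_fixdur = 0.25,   # log shrink of fixation durations per unit d
  sv_speed = 0.30      # log speed-up of saccades per unit d
)

#' Cohort configuration for the synthetic session generator
#'
#' Defaults mirror the study conditions: 40 participants, two game domains,
#' three games per domain, five questions per game, and a 5/6 probability of
#' a correct answer (a ~5:1 right:wrong imbalance).
#'
#' @param n_participants number of participants (>= 1)
#' @param n_games_per_domain games per domain (>= 1)
#' @param n_questions_per_game questions per game (>= 1)
#' @param p_correct probability a question is answered correctly, in (0,1)
#' @param gaze_hz,eda_hz,hr_hz,skeleton_hz sampling rates (Hz, > 0)
#' @param phase_duration_meanlog,phase_duration_sdlog lognormal parameters
#'   (seconds) of the See-Solve, Move and Respond phase durations
#' @param rest_s length of the question-free rest period opening each
#'   session; must cover the 30 s normalization baseline
#' @param seed integer seed; the cohort is a deterministic function of it
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_participants = 40L,
                          n_games_per_domain = 3L,
                          n_questions_per_game = 5L,
                          p_correct = 5 / 6,
                          gaze_hz = 50, eda_hz = 64, hr_hz = 1,
                          skeleton_hz = 1,
                          phase_duration_meanlog = log(c(
                            see_solve = 6, move = 2, respond = 2
                          )),
                          phase_duration_sdlog = c(
                            see_solve = 0.3, move = 0.3, respond = 0.3
                          ),
                          rest_s = 35,
                          seed = 1L) {
  stopifnot(
    n_participants >= 1, n_games_per_domain >= 1,
    n_questions_per_game >= 1,
    p_correct > 0, p_correct < 1,
    gaze_hz > 0, eda_hz > 0, hr_hz > 0, skeleton_hz > 0,
    rest_s >= 30
  )
  structure(
    list(
      n_participants = as.integer(n_participants),
      domains = c("arithmetic", "literacy"),
      n_games_per_domain = as.integer(n_games_per_domain),
      n_questions_per_game = as.integer(n_questions_per_game),
      p_correct = p_correct,
      gaze_hz = gaze_hz, eda_hz = eda_hz, hr_hz = hr_hz,
      skeleton_hz = skeleton_hz,
      phase_duration_meanlog = phase_duration_meanlog,
      phase_duration_sdlog = phase_duration_sdlog,
      rest_s = rest_s,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Planted effect specification
#'
#' Describes a standardized group difference planted on the raw channel a
#' measurement summarizes: the affinity label's cycles are shifted upward by
#' `d * channel_sd` within each phase.
#'
#' @param measurement one of [supported_measurements()]
#' @param affinity which label ("right"/"wrong") carries the higher value
#' @param d_see_solve,d_move,d_respond standardized mean differences (>= 0)
#' @return an `effect_spec` list
#' @export
effect_spec <- function(measurement, affinity,
                        d_see_solve = 0, d_move = 0, d_respond = 0) {
  if (!measurement %in% supported_measurements()) {
    stopf(
      "unknown measurement '%s'; supported: %s", measurement,
      paste(supported_measurements(), collapse = ", ")
    )
  }
  d <- c(
    see_solve = d_see_solve, move = d_move, respond = d_respond
  )
  stopifnot(all(d >= 0))
  if (any(d > 0)) {
    stopifnot(affinity %in% c("right", "wrong"))
  }
  structure(
    list(measurement = measurement, affinity = affinity, d = d),
    class = "effect_spec"
  )
}

# Validate a list of effect specs and index them by measurement.
index_effects <- function(effects) {
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  for (e in effects) {
    if (!inherits(e, "effect_spec")) {
      stopf("effects must be a list of effect_spec objects")
    }
  }
  setNames(effects, vapply(effects, `[[`, "", "measurement"))
}

# per-phase shift (in raw channel units) for a given cycle label
effect_shift <- function(effects, measurement, label, ref_sd) {
  e <- effects[[measurement]]
  if (is.null(e) || e$affinity != label) {
    return(c(see_solve = 0, move = 0, respond = 0))
  }
  e$d * ref_sd
}

#' Draw a participant physiological/behavioral profile
#'
#' Samples the per-participant baselines the generator builds streams from
#' (resting heart rate, pupil diameter, tonic skin conductance level, SCR
#' rate, fixation habits). Uses the current RNG state.
#'
#' @return a named list of profile parameters
#' @export
participant_profile <- function() {
  list(
    hr_base = rnorm(1, 88, 8), # children at play: wide between-subject SD
    hr_phi = 0.5, hr_sd = 2.5,
    pupil_base = rnorm(1, 3.2, 0.35),
    pupil_sd = 0.12,
    tonic_base = max(0.5, rnorm(1, 2.5, 0.8)),
    tonic_slope = rnorm(1, 0, 4e-4),
    tonic_phase = runif(1, 0, 2 * pi),
    scr_rate = rgamma(1, shape = 9, rate = 60), # ~0.15 events/s
    scr_amp_med = 0.15,
    fix_dur_med = 0.35,
    p_between = 0.45,
    blink_rate = 0.12
  )
}

# ---------------------------------------------------------------------------
# geometry

# AOI slots: question basket row at the bottom, three option rows on top
make_layout <- function() {
  slots <- list(
    c(0.05, 0.08, 0.30, 0.28),
    c(0.375, 0.08, 0.625, 0.28),
    c(0.70, 0.08, 0.95, 0.28)
  )
  correct_slot <- sample.int(3L, 1L)
  options <- lapply(seq_len(3L), function(i) {
    list(rect = slots[[i]], correct = i == correct_slot)
  })
  list(question = c(0.15, 0.72, 0.85, 0.92), options = options)
}

rect_center <- function(rect) c((rect[1] + rect[3]) / 2, (rect[2] + rect[4]) / 2)

aoi_point <- function(rect) {
  c(
    min(max(rect_center(rect)[1] + rnorm(1, 0, 0.03), rect[1] + 0.01), rect[3] - 0.01),
    min(max(rect_center(rect)[2] + rnorm(1, 0, 0.02), rect[2] + 0.01), rect[4] - 0.01)
  )
}

neutral_point <- function() c(runif(1, 0.25, 0.75), runif(1, 0.45, 0.62))

snap <- function(x) round(x / GAZE_DT) * GAZE_DT

# ---------------------------------------------------------------------------
# gaze event assembly
#
# Events are accumulated as "segments": fixations (constant target) and
# saccades (linear sweep), each an exact number of 50 Hz samples, laid end to
# end so the sample grid is gapless. A saccade *precedes* the fixation it
# lands on, so a fixation scheduled at time t starts exactly at t.

new_segment_buf <- function() new.env(parent = emptyenv())

seg_init <- function(buf) {
  buf$type <- character(0); buf$t0 <- numeric(0); buf$n <- integer(0)
  buf$x0 <- numeric(0); buf$y0 <- numeric(0)
  buf$x1 <- numeric(0); buf$y1 <- numeric(0)
  buf$cursor <- 0 # end time of last segment
  buf$pos <- c(0.5, 0.55)
  invisible(buf)
}

seg_push <- function(buf, type, n, to) {
  if (n <= 0) {
    buf$pos <- to
    return(invisible(buf))
  }
  i <- length(buf$type) + 1L
  buf$type[i] <- type
  buf$t0[i] <- buf$cursor
  buf$n[i] <- as.integer(n)
  buf$x0[i] <- buf$pos[1]; buf$y0[i] <- buf$pos[2]
  buf$x1[i] <- to[1]; buf$y1[i] <- to[2]
  buf$cursor <- buf$cursor + n * GAZE_DT
  buf$pos <- to
  invisible(buf)
}

# saccade to `to` then fixate there until `until` (end exclusive)
seg_saccade_fixate <- function(buf, to, until, speed_mult = 1) {
  amp <- sqrt(sum((to - buf$pos)^2))
  n_s <- if (amp < 0.12) 1L else max(2L, round(amp * 8 / speed_mult))
  # never overshoot the target end
  room <- round((until - buf$cursor) / GAZE_DT)
  if (room <= 0) return(invisible(buf))
  n_s <- min(n_s, room)
  seg_push(buf, "saccade", n_s, to)
  n_f <- round((until - buf$cursor) / GAZE_DT)
  if (n_f > 0) seg_push(buf, "fixation", n_f, to)
  invisible(buf)
}

# fill [cursor, until) with neutral wandering fixations
seg_fill_neutral <- function(buf, until) {
  while (buf$cursor < until - GAZE_DT / 2) {
    dur <- snap(min(rlnorm(1, log(0.45), 0.35), until - buf$cursor))
    seg_saccade_fixate(buf, neutral_point(), min(until, buf$cursor + max(dur, 0.1)))
  }
  invisible(buf)
}

# fill [cursor, until) scanning AOIs, starting with the question AOI at the
# cursor; returns nothing, mutates buf. p_between / fix_mult carry planted
# IPI modulation, speed_mult carries saccade-velocity modulation.
seg_fill_scan <- function(buf, until, layout, start_aoi = "question",
                          p_between, fix_mult, speed_mult, fix_dur_med) {
  aois <- c(list(question = layout$question), lapply(layout$options, `[[`, "rect"))
  names(aois) <- c("question", paste0("opt", seq_along(layout$options)))
  current <- start_aoi
  first <- TRUE
  while (buf$cursor < until - GAZE_DT / 2) {
    if (!first) {
      if (runif(1) < p_between) {
        current <- sample(setdiff(names(aois), current), 1L)
      }
    }
    target <- aoi_point(aois[[current]])
    dur <- snap(max(rlnorm(1, log(fix_dur_med * fix_mult), 0.4), 0.08))
    stop_at <- min(until, buf$cursor + dur + 0.06)
    if (first) {
      # land exactly at the scheduled start: saccade time is charged to the
      # preceding segment by the caller leaving room, so emit fixation first
      n_f <- round((min(until, buf$cursor + dur) - buf$cursor) / GAZE_DT)
      if (n_f > 0) seg_push(buf, "fixation", n_f, target)
      first <- FALSE
    } else {
      seg_saccade_fixate(buf, target, stop_at, speed_mult)
    }
  }
  invisible(buf)
}

# ---------------------------------------------------------------------------
# one question cycle

# Build the gaze segments, log entry, SCR events and ground truth of a single
# cycle. `buf` already holds gaze up to the question onset.
build_cycle <- function(buf, onset, profile, label, effects, cfg) {
  ml <- cfg$phase_duration_meanlog
  sl <- cfg$phase_duration_sdlog
  delay <- snap(max(rlnorm(1, log(0.5), 0.35), 0.1))
  dur <- c(
    see_solve = snap(max(rlnorm(1, ml[["see_solve"]], sl[["see_solve"]]), 1.5)),
    move = snap(max(rlnorm(1, ml[["move"]], sl[["move"]]), 0.8)),
    respond = snap(max(rlnorm(1, ml[["respond"]], sl[["respond"]]), 0.8))
  )
  ss_start <- onset + delay
  move_start <- ss_start + dur[["see_solve"]]
  selection <- move_start + dur[["move"]]
  response <- selection + dur[["respond"]]

  layout <- make_layout()
  correct_idx <- which(vapply(layout$options, `[[`, TRUE, "correct"))
  chosen <- if (label == "right") {
    correct_idx
  } else {
    sample(setdiff(seq_along(layout$options), correct_idx), 1L)
  }

  # behavioral modulation from planted gaze effects
  ipi_sh <- effect_shift(effects, "ipi", label, 1)
  sv_sh <- effect_shift(effects, "saccade_velocity", label, 1)
  p_btw <- stats::plogis(
    stats::qlogis(profile$p_between) + ipi_sh * CF_EFFECT_COEF[["ipi_logit"]]
  )
  fix_mult <- exp(-ipi_sh * CF_EFFECT_COEF[["ipi_fixdur"]])
  sv_mult <- exp(sv_sh * CF_EFFECT_COEF[["sv_speed"]])

  # neutral gaze until just before ss_start, then saccade onto the question
  q_target <- aoi_point(layout$question)
  sacc_n <- 3L
  seg_fill_neutral(buf, ss_start - sacc_n * GAZE_DT)
  n_s <- round((ss_start - buf$cursor) / GAZE_DT)
  if (n_s > 0) seg_push(buf, "saccade", n_s, q_target)
  buf$pos <- q_target
  seg_fill_scan(buf, move_start, layout,
    start_aoi = "question",
    p_between = p_btw[["see_solve"]], fix_mult = fix_mult[["see_solve"]],
    speed_mult = sv_mult[["see_solve"]], fix_dur_med = profile$fix_dur_med
  )
  # move: gaze sits on the chosen option
  opt_rect <- layout$options[[chosen]]$rect
  seg_saccade_fixate(buf, aoi_point(opt_rect),
    min(selection, buf$cursor + snap(rlnorm(1, log(0.5), 0.3))),
    sv_mult[["move"]]
  )
  seg_fill_scan(buf, selection, layout,
    start_aoi = paste0("opt", chosen),
    p_between = p_btw[["move"]] * 0.4, fix_mult = fix_mult[["move"]],
    speed_mult = sv_mult[["move"]], fix_dur_med = profile$fix_dur_med
  )
  # respond: pursuit of the dragged option toward the question basket,
  # approximated by short fixations along the path
  path_from <- rect_center(opt_rect)
  path_to <- rect_center(layout$question)
  n_steps <- max(2L, round(dur[["respond"]] / 0.45))
  step_until <- seq(selection, response, length.out = n_steps + 1L)[-1]
  for (k in seq_len(n_steps)) {
    frac <- k / n_steps
    p <- path_from + frac * (path_to - path_from) + rnorm(2, 0, 0.015)
    seg_saccade_fixate(buf, p, snap(step_until[k]), sv_mult[["respond"]])
  }
  if (buf$cursor < response - 1e-9) {
    seg_push(buf, "fixation", round((response - buf$cursor) / GAZE_DT), buf$pos)
  }

  # SCR events: piecewise-constant Poisson rate over the cycle
  pk_sh <- effect_shift(effects, "eda_peaks", label, 1)
  bounds <- c(onset, ss_start, move_start, selection, response)
  phases <- c("pre", "see_solve", "move", "respond")
  scr_t <- numeric(0)
  for (i in seq_along(phases)) {
    rate <- profile$scr_rate
    if (phases[i] != "pre") {
      rate <- rate * (1 + pk_sh[[phases[i]]] * CF_EFFECT_COEF[["peaks_mult"]])
    }
    span <- bounds[i + 1] - bounds[i]
    k <- rpois(1, rate * span)
    if (k > 0) scr_t <- c(scr_t, sort(runif(k, bounds[i], bounds[i + 1])))
  }
  ph_sh <- effect_shift(effects, "phasic_eda", label, 1)
  scr_amp <- rlnorm(length(scr_t), log(profile$scr_amp_med), 0.5)
  if (length(scr_t)) {
    ph_idx <- findInterval(scr_t, bounds[2:5]) # 0 = pre
    mult <- c(1, 1 + ph_sh * CF_EFFECT_COEF[["phasic_mult"]])[ph_idx + 1L]
    scr_amp <- scr_amp * mult
  }

  list(
    log_entry = list(
      onset = onset, selection = selection, response = response,
      chosen = chosen, correct = label == "right", layout = layout
    ),
    truth = data.table(
      phase = c("see_solve", "move", "respond"),
      t_start = c(ss_start, move_start, selection),
      t_end = c(move_start, selection, response)
    ),
    onset = onset, ss_start = ss_start, move_start = move_start,
    selection = selection, response = response, label = label,
    scr_t = scr_t, scr_amp = scr_amp,
    scr_phase_count = {
      if (length(scr_t)) {
        idx <- findInterval(scr_t, bounds[2:5])
        tabulate(idx[idx >= 1 & idx <= 3], 3L)
      } else {
        c(0L, 0L, 0L)
      }
    }
  )
}

# ---------------------------------------------------------------------------
# stream materialization

materialize_gaze <- function(buf, profile, effects, cycles, cfg) {
  n_tot <- sum(buf$n)
  x <- numeric(n_tot)
  y <- numeric(n_tot)
  pos <- 1L
  for (i in seq_along(buf$n)) {
    n <- buf$n[i]
    idx <- pos:(pos + n - 1L)
    if (buf$type[i] == "fixation") {
      x[idx] <- buf$x1[i] + rnorm(n, 0, 0.004)
      y[idx] <- buf$y1[i] + rnorm(n, 0, 0.004)
    } else {
      # the sweep reaches the target on its last sample, so the following
      # fixation's first sample is already slow
      fr <- seq_len(n) / n
      x[idx] <- buf$x0[i] + fr * (buf$x1[i] - buf$x0[i])
      y[idx] <- buf$y0[i] + fr * (buf$y1[i] - buf$y0[i])
    }
    pos <- pos + n
  }
  t <- seq(0, by = GAZE_DT, length.out = n_tot)

  # pupil: slow AR(1) wander + planted cognitive-load shifts + sensor noise
  wander <- as.numeric(stats::filter(
    rnorm(n_tot, 0, profile$pupil_sd * sqrt(1 - 0.98^2)), 0.98,
    method = "recursive"
  ))
  shift <- phase_shift_vector(
    t, cycles, effects, "cognitive_load", CF_REF_SD[["cognitive_load"]]
  )
  pupil <- profile$pupil_base + wander + shift
  pupil_l <- pupil + rnorm(n_tot, 0, 0.03)
  pupil_r <- pupil + rnorm(n_tot, 0, 0.03)

  # blinks: short invalid runs, vetoed near planted See-Solve onsets so the
  # ground-truth first question fixation stays observable
  valid <- rep(1L, n_tot)
  T_end <- t[n_tot]
  n_blinks <- rpois(1, profile$blink_rate * T_end)
  if (n_blinks > 0) {
    b_start <- runif(n_blinks, 0, T_end)
    b_dur <- runif(n_blinks, 0.1, 0.25)
    guard_lo <- vapply(cycles, function(cy) cy$ss_start, 0) - 0.06
    guard_hi <- guard_lo + 0.51
    for (b in seq_len(n_blinks)) {
      if (any(b_start[b] < guard_hi & b_start[b] + b_dur[b] > guard_lo)) next
      idx <- which(t >= b_start[b] & t < b_start[b] + b_dur[b])
      valid[idx] <- 0L
    }
  }
  pupil_l[valid == 0L] <- NA_real_
  pupil_r[valid == 0L] <- NA_real_

  data.table(
    t = t, x = x, y = y, pupil_l = pupil_l, pupil_r = pupil_r, valid = valid
  )
}

# additive shift evaluated on a time grid for level-planted channels
phase_shift_vector <- function(t, cycles, effects, measurement, ref_sd) {
  out <- numeric(length(t))
  e <- effects[[measurement]]
  if (is.null(e) || all(e$d == 0)) return(out)
  for (cy in cycles) {
    if (cy$label != e$affinity) next
    tr <- cy$truth
    for (r in seq_len(nrow(tr))) {
      d <- e$d[[tr$phase[r]]]
      if (d > 0) {
        out[t >= tr$t_start[r] & t < tr$t_end[r]] <- d * ref_sd
      }
    }
  }
  out
}

scr_kernel <- function(s, tau_rise = 0.75, tau_decay = 3) {
  h <- exp(-s / tau_decay) - exp(-s / tau_rise)
  t_peak <- log(tau_decay / tau_rise) * tau_decay * tau_rise /
    (tau_decay - tau_rise)
  h / (exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise))
}

materialize_eda <- function(T_end, profile, effects, cycles, cfg) {
  t <- seq(0, T_end, by = 1 / cfg$eda_hz)
  tonic <- profile$tonic_base + profile$tonic_slope * t +
    0.15 * sin(2 * pi * t / 180 + profile$tonic_phase)
  tonic <- tonic + phase_shift_vector(
    t, cycles, effects, "tonic_eda", CF_REF_SD[["tonic_eda"]]
  )
  sig <- tonic
  for (cy in cycles) {
    for (k in seq_along(cy$scr_t)) {
      te <- cy$scr_t[k]
      idx <- which(t >= te & t <= te + 10)
      if (length(idx)) {
        sig[idx] <- sig[idx] + cy$scr_amp[k] * scr_kernel(t[idx] - te)
      }
    }
  }
  sig <- sig + rnorm(length(t), 0, 0.008)
  data.table(t = t, eda = pmax(sig, 0.01))
}

materialize_hr <- function(T_end, profile, effects, cycles, cfg) {
  t <- seq(0, T_end, by = 1 / cfg$hr_hz)
  ar <- as.numeric(stats::filter(
    rnorm(length(t), 0, profile$hr_sd * sqrt(1 - profile$hr_phi^2)),
    profile$hr_phi,
    method = "recursive"
  ))
  shift <- phase_shift_vector(
    t, cycles, effects, "mean_hr", CF_REF_SD[["mean_hr"]]
  )
  data.table(t = t, hr = profile$hr_base + ar + shift)
}

# canonical 25-joint standing pose (meters, sensor coordinates)
base_skeleton <- function() {
  set <- rbind(
    c(0, 1.60, 2.5), c(0, 1.40, 2.5), c(0, 1.15, 2.5), c(0, 0.95, 2.5),
    c(-0.20, 1.38, 2.5), c(-0.32, 1.15, 2.5), c(-0.35, 0.92, 2.48),
    c(-0.36, 0.85, 2.47),
    c(0.20, 1.38, 2.5), c(0.32, 1.15, 2.5), c(0.35, 0.92, 2.48),
    c(0.36, 0.85, 2.47),
    c(-0.10, 0.90, 2.5), c(-0.12, 0.50, 2.5), c(-0.13, 0.08, 2.5),
    c(-0.14, 0.02, 2.42),
    c(0.10, 0.90, 2.5), c(0.12, 0.50, 2.5), c(0.13, 0.08, 2.5),
    c(0.14, 0.02, 2.42),
    c(0, 1.30, 2.5), c(-0.37, 0.80, 2.46), c(-0.38, 0.78, 2.46),
    c(0.37, 0.80, 2.46), c(0.38, 0.78, 2.46)
  )
  set
}

materialize_skeleton <- function(T_end, cycles, cfg) {
  t <- seq(0, T_end, by = 1 / cfg$skeleton_hz)
  n <- length(t)
  base <- base_skeleton()
  moving <- logical(n)
  for (cy in cycles) {
    moving <- moving | (t >= cy$move_start & t < cy$response)
  }
  # idle motion = whole-body postural sway (bounded, slow oscillation) plus
  # tiny sensor noise; answering motion = large whole-body steps
  frames <- matrix(0, n, 75)
  jitter <- matrix(rnorm(n * 75, 0, 2e-4), n, 75)
  base_row <- as.numeric(t(base))
  frames <- sweep(jitter, 2, base_row, `+`)
  sway_phase <- runif(1, 0, 2 * pi)
  sway <- 0.004 * sin(2 * pi * 0.3 * t + sway_phase)
  x_cols <- seq(1, 73, 3)
  z_cols <- seq(3, 75, 3)
  frames[, x_cols] <- frames[, x_cols] + sway
  frames[, z_cols] <- frames[, z_cols] + sway * 0.8
  step <- matrix(rnorm(n * 75, 0, 0.04), n, 75) * moving
  # moving frames wander away from the pose (cumulative within each bout)
  bout <- cumsum(c(0, diff(moving)) == 1) * moving
  if (any(moving)) {
    for (b in unique(bout[bout > 0])) {
      idx <- which(bout == b)
      frames[idx, ] <- frames[idx, ] + apply(step[idx, , drop = FALSE], 2, cumsum)
    }
  }
  dt <- data.table(t = t)
  joints <- paste0(
    "j", rep(sprintf("%02d", 1:25), each = 3), "_", rep(c("x", "y", "z"), 25)
  )
  for (j in seq_along(joints)) dt[[joints[j]]] <- frames[, j]
  dt
}

# ---------------------------------------------------------------------------
# session + cohort

#' Generate one participant session
#'
#' One continuous recording: a rest period, then all games of both domains.
#' Deterministic given `seed`.
#'
#' @param config a [cohort_config()]
#' @param effects list of [effect_spec()] objects
#' @param participant_id identifier string
#' @param seed integer seed for this session
#' @return a `session_bundle` list with elements `participant_id`, `gaze`,
#'   `eda`, `hr`, `skeleton`, `log` and `ground_truth`
#' @export
generate_session <- function(config, effects = list(), participant_id = "p01",
                             seed = 1L) {
  effects <- index_effects(effects)
  set.seed(seed)
  profile <- participant_profile()

  buf <- new_segment_buf()
  seg_init(buf)
  seg_fill_neutral(buf, config$rest_s)

  cycles <- list()
  log_rows <- list()
  qid <- 0L
  for (d in seq_along(config$domains)) {
    if (d > 1) seg_fill_neutral(buf, buf$cursor + 5)
    for (g in seq_len(config$n_games_per_domain)) {
      if (g > 1) seg_fill_neutral(buf, buf$cursor + 3)
      for (q in seq_len(config$n_questions_per_game)) {
        qid <- qid + 1L
        gap <- snap(max(rlnorm(1, log(1.5), 0.25), 0.6))
        onset <- snap(buf$cursor + gap)
        label <- if (runif(1) < config$p_correct) "right" else "wrong"
        cy <- build_cycle(buf, onset, profile, label, effects, config)
        cy$domain <- config$domains[d]
        cy$game <- g
        cy$question <- qid
        cycles[[qid]] <- cy
        log_rows[[qid]] <- c(
          list(
            question_id = qid, domain = config$domains[d], game = g
          ),
          cy$log_entry
        )
      }
    }
  }
  seg_fill_neutral(buf, buf$cursor + 3)

  gaze <- materialize_gaze(buf, profile, effects, cycles, config)
  T_end <- max(gaze$t)
  eda <- materialize_eda(T_end, profile, effects, cycles, config)
  hr <- materialize_hr(T_end, profile, effects, cycles, config)
  skeleton <- materialize_skeleton(T_end, cycles, config)

  log_dt <- rbindlist(lapply(log_rows, function(r) {
    data.table(
      question_id = r$question_id, domain = r$domain, game = r$game,
      onset = r$onset, selection = r$selection, response = r$response,
      chosen = r$chosen, correct = r$correct
    )
  }))
  layouts <- lapply(log_rows, `[[`, "layout")
  names(layouts) <- as.character(log_dt$question_id)

  truth <- rbindlist(lapply(cycles, function(cy) {
    tr <- copy(cy$truth)
    tr[, `:=`(
      participant = participant_id, domain = cy$domain, game = cy$game,
      question = cy$question, label = cy$label
    )]
    tr
  }))
  truth <- cbind(
    truth,
    channel_summaries(cycles, gaze, hr, eda, profile)
  )

  structure(
    list(
      participant_id = participant_id,
      gaze = gaze, eda = eda, hr = hr, skeleton = skeleton,
      log = log_dt, layouts = layouts,
      ground_truth = list(
        cycles = truth, effects = effects, profile = profile
      )
    ),
    class = "session_bundle"
  )
}

# raw per-cycle-phase channel means, the oracle surface for planted-effect
# recovery: computed directly on the generated streams
channel_summaries <- function(cycles, gaze, hr, eda, profile) {
  starts <- unlist(lapply(cycles, function(cy) cy$truth$t_start))
  ends <- unlist(lapply(cycles, function(cy) cy$truth$t_end))
  pupil <- (gaze$pupil_l + gaze$pupil_r) / 2
  pupil[gaze$valid == 0L] <- NA_real_
  data.table(
    hr_mean = window_mean(hr$t, hr$hr, starts, ends),
    pupil_mean = window_mean(gaze$t, pupil, starts, ends),
    scr_count = unlist(lapply(cycles, function(cy) cy$scr_phase_count))
  )
}

#' Generate a synthetic cohort
#'
#' Deterministic for a fixed `config$seed`: the cohort RNG stream is split
#' per participant by a counter, so bundles do not depend on generation
#' order.
#'
#' @param config a [cohort_config()]
#' @param effects list of [effect_spec()] objects (possibly empty)
#' @return list of `session_bundle` objects, one per participant
#' @export
generate_cohort <- function(config, effects = list()) {
  stopifnot(inherits(config, "cohort_config"))
  effects <- index_effects(effects)
  ids <- sprintf("p%02d", seq_len(config$n_participants))
  lapply(seq_len(config$n_participants), function(i) {
    generate_session(
      config, effects, ids[i],
      seed = derive_seed(config$seed, i)
    )
  })
}

#' Generate a single standalone question cycle
#'
#' Produces the raw streams and log entry of one question cycle preceded by a
#' short neutral lead-in, using a supplied participant profile. Mainly a test
#' surface for the phase-segmentation contract: the first question-AOI
#' fixation starts at the true See-Solve onset, the skeletal excursion at the
#' true Move onset, and the logged selection/response at the true Respond
#' boundaries.
#'
#' @param profile a [participant_profile()] list
#' @param correctness "right" or "wrong"
#' @param effects list of [effect_spec()] objects
#' @param seed integer seed
#' @param lead_s neutral lead-in seconds before the question onset
#' @return list with `gaze`, `eda`, `hr`, `skeleton`, `log_entry`, `layout`
#'   and `truth` (the three phase boundaries)
#' @export
generate_question_cycle <- function(profile, correctness, effects = list(),
                                    seed = 1L, lead_s = 5) {
  stopifnot(correctness %in% c("right", "wrong"))
  effects <- index_effects(effects)
  set.seed(seed)
  cfg <- cohort_config(seed = seed)
  buf <- new_segment_buf()
  seg_init(buf)
  seg_fill_neutral(buf, lead_s)
  onset <- snap(buf$cursor + 1)
  cy <- build_cycle(buf, onset, profile, correctness, effects, cfg)
  seg_fill_neutral(buf, buf$cursor + 2)
  cycles <- list(cy)
  gaze <- materialize_gaze(buf, profile, effects, cycles, cfg)
  T_end <- max(gaze$t)
  list(
    gaze = gaze,
    eda = materialize_eda(T_end, profile, effects, cycles, cfg),
    hr = materialize_hr(T_end, profile, effects, cycles, cfg),
    skeleton = materialize_skeleton(T_end, cycles, cfg),
    log_entry = cy$log_entry,
    layout = cy$log_entry$layout,
    truth = cy$truth
  )
}
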