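# Gaze event detection, pupil and baseline normalization, EDA
# decomposition and windowing.

test_that("a static gaze point yields exactly one fixation", {
  set.seed(1)
  g <- make_gaze_dwells(list(c(0.5, 0.5, 1.0)), jitter = 0.003)
  ev <- detect_gaze_events(g, 1.0)
  expect_equal(nrow(ev[kind == "fixation"]), 1L)
  expect_equal(nrow(ev[kind == "saccade"]), 0L)
  expect_equal(ev$x[1], 0.5, tolerance = 0.01)
})

test_that("two distant clusters yield two fixations and one saccade", {
  set.seed(2)
  g <- make_gaze_dwells(
    list(c(0.2, 0.2, 0.5), c(0.8, 0.8, 0.5)),
    jitter = 0.002
  )
  ev <- detect_gaze_events(g, 1.0)
  expect_equal(nrow(ev[kind == "fixation"]), 2L)
  sac <- ev[kind == "saccade"]
  expect_equal(nrow(sac), 1L)
  expect_equal(sac$amplitude, sqrt(2 * 0.6^2), tolerance = 0.05)
})

test_that("sample labels match a brute-force velocity classifier", {
  for (s in 1:5) {
    set.seed(s)
    n <- 400
    g <- data.table(
      t = (seq_len(n) - 1) / 50,
      x = cumsum(rnorm(n, 0, 0.01)),
      y = cumsum(rnorm(n, 0, 0.01)),
      pupil_l = 3, pupil_r = 3, valid = 1L
    )
    for (thr in c(0.3, 0.6, 1.2)) {
      lab <- ivt_classify_samples(g, thr)
      v_oracle <- c(0, sqrt(diff(g$x)^2 + diff(g$y)^2) / diff(g$t))
      expect_identical(lab, ifelse(v_oracle > thr, "saccade", "fixation"))
    }
  }
})

test_that("invalid runs become blink events and all-invalid input flags", {
  set.seed(3)
  g <- make_gaze_dwells(list(c(0.5, 0.5, 1.0)), jitter = 0.002)
  g[20:30, `:=`(valid = 0L, pupil_l = NA_real_, pupil_r = NA_real_)]
  ev <- detect_gaze_events(g, 1.0)
  expect_equal(nrow(ev[kind == "blink"]), 1L)
  g_all <- copy(g)[, `:=`(valid = 0L, pupil_l = NA_real_, pupil_r = NA_real_)]
  ev2 <- detect_gaze_events(g_all, 1.0)
  expect_equal(nrow(ev2), 0L)
  expect_true(isTRUE(attr(ev2, "all_invalid")))
})

test_that("event detection is invariant under a uniform time shift", {
  set.seed(4)
  g <- make_gaze_dwells(
    list(c(0.2, 0.2, 0.4), c(0.7, 0.7, 0.4), c(0.3, 0.6, 0.4)),
    jitter = 0.002
  )
  ev1 <- detect_gaze_events(g, 1.0)
  g2 <- copy(g)[, t := t + 100]
  ev2 <- detect_gaze_events(g2, 1.0)
  expect_identical(ev1$kind, ev2$kind)
  expect_equal(ev2$t_start - 100, ev1$t_start, tolerance = 1e-9)
  expect_equal(ev1$amplitude, ev2$amplitude, tolerance = 1e-12)
  # amplitudes invariant under screen translation
  g3 <- copy(g)[, `:=`(x = x + 0.05, y = y - 0.05)]
  ev3 <- detect_gaze_events(g3, 1.0)
  expect_equal(ev1$amplitude, ev3$amplitude, tolerance = 1e-12)
})

test_that("pupil normalization z-scores against the participant baseline", {
  # baseline mean 3 mm, SD 0.5: a 4 mm sample maps to 2.0
  set.seed(5)
  n <- 1600
  base_vals <- rep(c(2.5, 3.5), n / 2) # mean 3, sd ~0.5
  g <- data.table(
    t = (seq_len(n) - 1) / 50,
    x = 0.5, y = 0.5,
    pupil_l = base_vals, pupil_r = base_vals, valid = 1L
  )
  g$pupil_l[n] <- 4
  g$pupil_r[n] <- 4
  p <- normalize_pupil(g, baseline = c(0, 30))
  s <- sd(base_vals[1:1500])
  expect_equal(p$pupil[n], (4 - mean(base_vals[1:1500])) / s, tolerance = 1e-6)
  # a series identical to its baseline normalizes to ~0 on average
  p2 <- normalize_pupil(g[1:1500], baseline = c(0, 30))
  expect_equal(mean(p2$pupil), 0, tolerance = 1e-8)
  # empty baseline errors
  g3 <- copy(g)[, `:=`(valid = 0L, pupil_l = NA_real_, pupil_r = NA_real_)]
  expect_error(normalize_pupil(g3, c(0, 30)), "baseline")
})

test_that("EDA decomposition reconstructs and splits a bump into phasic", {
  t <- seq(0, 60, by = 1 / 64)
  # constant signal: tonic = signal, phasic = 0
  dec0 <- decompose_eda(data.table(t = t, eda = rep(2, length(t))))
  expect_equal(dec0$tonic, rep(2, length(t)), tolerance = 1e-12)
  expect_equal(dec0$phasic, rep(0, length(t)), tolerance = 1e-12)
  # slow ramp + one ~2 s bump: the decomposition sends nearly all of the
  # (smoothed) bump energy to the phasic component, not the tonic one
  ramp <- 2 + 0.002 * t
  bump <- 0.3 * exp(-(t - 30)^2 / (2 * 0.35^2))
  dec <- decompose_eda(data.table(t = t, eda = ramp + bump))
  dec_ramp <- decompose_eda(data.table(t = t, eda = ramp))
  bump_smoothed <- dec$smoothed - dec_ramp$smoothed
  sel <- t > 28 & t < 32
  expect_gt(sum(dec$phasic[sel]^2) / sum(bump_smoothed[sel]^2), 0.9)
  # reconstruction identity on random signals
  for (s in 1:5) {
    set.seed(s)
    x <- cumsum(rnorm(2000, 0, 0.01)) + 2
    dec2 <- decompose_eda(data.table(t = seq_along(x) / 64, eda = x))
    expect_equal(dec2$tonic + dec2$phasic, dec2$smoothed, tolerance = 1e-12)
  }
})

test_that("leading-baseline normalization matches hand arithmetic", {
  t <- 0:59
  x <- c(rep(c(8, 12), 15), rep(10, 30)) # first 30 s: mean 10, sd ~2
  z <- baseline_normalize(t, x, 30)
  s <- sd(x[t < 30])
  expect_equal(z[31], (10 - 10) / s)
  x2 <- x
  x2[41] <- 14
  z2 <- baseline_normalize(t, x2, 30)
  expect_equal(z2[41], 4 / s)
  # constant baseline divides by 1 and raises the flag
  z3 <- baseline_normalize(t, rep(7, 60), 30)
  expect_true(attr(z3, "constant_baseline"))
  expect_equal(as.numeric(z3), rep(0, 60))
  # too-short stream errors
  expect_error(baseline_normalize(0:10, rnorm(11), 30), "shorter")
})

test_that("windowing tiles intervals at the hop with the half-length rule", {
  w <- make_windows(0, 20, 10, 5)
  expect_equal(nrow(w), 3L)
  expect_equal(w$t_start, c(0, 5, 10))
  # a 7 s interval keeps its single long-enough truncated window
  w2 <- make_windows(0, 7, 10, 5)
  expect_equal(nrow(w2), 1L)
  expect_equal(w2$t_end - w2$t_start, 7)
  # full-window count formula on random intervals
  for (s in 1:10) {
    set.seed(s)
    L <- runif(1, 12, 120)
    w3 <- make_windows(0, L, 10, 5)
    full <- sum(w3$t_end - w3$t_start >= 10 - 1e-9)
    expect_equal(full, floor((L - 10) / 5) + 1)
    # starts form an arithmetic sequence at the hop
    expect_equal(diff(w3$t_start), rep(5, nrow(w3) - 1))
  }
})

test_that("windows take the phase of the segment containing their midpoint", {
  segs <- data.table(
    question = c(1L, 1L, 1L),
    phase = c("see_solve", "move", "respond"),
    t_start = c(2, 8, 10), t_end = c(8, 10, 13)
  )
  w <- make_windows(0, 20, 10, 5)
  aw <- assign_window_phase(w, segs)
  # midpoints 5, 10, 15 -> see_solve, respond, outside
  expect_identical(aw$phase, c("see_solve", "respond", NA))
  expect_identical(aw$question, c(1L, 1L, NA))
})
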