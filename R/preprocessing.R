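# Raw-stream preprocessing: gaze event classification, pupil normalization,
# EDA smoothing/decomposition, leading-baseline normalization and the
# overlapping analysis windows.

#' Per-sample I-VT classification
#'
#' Labels every gaze sample `"fixation"`, `"saccade"` or `"blink"` from its
#' point-to-point velocity: invalid samples (validity flag 0 or both pupils
#' missing) are blinks; otherwise a sample is a saccade when the velocity on
#' the segment ending at it exceeds the threshold. The first valid sample is
#' a fixation by convention.
#'
#' @param gaze data.table with `t`, `x`, `y`, `pupil_l`, `pupil_r`, `valid`
#' @param velocity_threshold screen units per second
#' @return character vector of per-sample labels
#' @export
ivt_classify_samples <- function(gaze, velocity_threshold) {
  n <- nrow(gaze)
  invalid <- gaze$valid == 0L | (is.na(gaze$pupil_l) & is.na(gaze$pupil_r))
  v <- c(
    0,
    sqrt(diff(gaze$x)^2 + diff(gaze$y)^2) / diff(gaze$t)
  )
  # velocity across a blink boundary is undefined; treat as slow
  v[is.na(v)] <- 0
  lab <- ifelse(v > velocity_threshold, "saccade", "fixation")
  lab[which(invalid)] <- "blink"
  # a "saccade" sample right after a blink is a re-entry artifact
  after_blink <- which(invalid) + 1L
  after_blink <- after_blink[after_blink <= n]
  lab[after_blink[lab[after_blink] == "saccade"]] <- "fixation"
  lab
}

#' Detect fixations, saccades and blinks (I-VT)
#'
#' Velocity-threshold classification of raw gaze samples followed by merging
#' of adjacent same-kind samples into events. Fixations shorter than
#' `min_fixation_s` are relabelled as saccade when flanked by saccades,
#' otherwise discarded.
#'
#' @param gaze data.table with `t`, `x`, `y`, `pupil_l`, `pupil_r`, `valid`
#' @param velocity_threshold screen units per second
#' @param min_fixation_s minimum fixation duration (default 60 ms)
#' @return data.table of events: `kind`, `t_start`, `t_end`, `x`, `y`
#'   (fixation centroid), `amplitude`, `peak_velocity`; empty with attribute
#'   `all_invalid = TRUE` when no valid samples exist
#' @export
detect_gaze_events <- function(gaze, velocity_threshold = 1.0,
                               min_fixation_s = 0.06) {
  empty <- data.table(
    kind = character(0), t_start = numeric(0), t_end = numeric(0),
    x = numeric(0), y = numeric(0), amplitude = numeric(0),
    peak_velocity = numeric(0)
  )
  if (nrow(gaze) < 2L) {
    return(empty)
  }
  lab <- ivt_classify_samples(gaze, velocity_threshold)
  if (all(lab == "blink")) {
    attr(empty, "all_invalid") <- TRUE
    return(empty)
  }
  dt <- median(diff(gaze$t))
  v <- c(0, sqrt(diff(gaze$x)^2 + diff(gaze$y)^2) / diff(gaze$t))

  build_events <- function(lab) {
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    data.table(
      kind = r$values,
      i_start = starts, i_end = ends
    )
  }
  ev <- build_events(lab)
  # short-fixation rule
  dur <- (ev$i_end - ev$i_start + 1L) * dt
  short_fix <- which(ev$kind == "fixation" & dur < min_fixation_s)
  drop <- logical(nrow(ev))
  for (i in short_fix) {
    prev_k <- if (i > 1) ev$kind[i - 1] else NA
    next_k <- if (i < nrow(ev)) ev$kind[i + 1] else NA
    if (identical(prev_k, "saccade") && identical(next_k, "saccade")) {
      ev$kind[i] <- "saccade"
    } else {
      drop[i] <- TRUE
    }
  }
  keep <- !drop
  # re-merge adjacent same-kind runs after relabelling
  lab2 <- rep(ev$kind[keep], times = (ev$i_end - ev$i_start + 1L)[keep])
  idx2 <- unlist(lapply(which(keep), function(i) ev$i_start[i]:ev$i_end[i]))
  ev2 <- build_events(lab2)
  # grouped aggregation over the runs
  run_id <- rep(seq_len(nrow(ev2)), ev2$i_end - ev2$i_start + 1L)
  samp <- idx2
  agg <- data.table(
    g = run_id, x = gaze$x[samp], y = gaze$y[samp], v = v[samp]
  )[, .(mx = mean(x), my = mean(y), pv = max(v)), by = g]
  first <- idx2[ev2$i_start]
  last <- idx2[ev2$i_end]
  i0 <- pmax(first - 1L, 1L)
  out <- data.table(
    kind = ev2$kind,
    t_start = gaze$t[first],
    t_end = gaze$t[last] + dt,
    x = agg$mx, y = agg$my,
    amplitude = sqrt(
      (gaze$x[last] - gaze$x[i0])^2 + (gaze$y[last] - gaze$y[i0])^2
    ),
    peak_velocity = agg$pv
  )
  out[kind != "fixation", `:=`(x = NA_real_, y = NA_real_)]
  out[kind != "saccade", `:=`(
    amplitude = NA_real_, peak_velocity = NA_real_
  )]
  out[]
}

#' Normalize pupil diameter against a participant baseline
#'
#' Averages the two eyes where both are valid (single eye otherwise),
#' removes blink samples, and z-scores against the baseline interval.
#'
#' @param gaze gaze sample table
#' @param baseline interval `c(start, end)` in seconds
#' @return data.table `t`, `pupil` (z-scored); blink samples removed
#' @export
normalize_pupil <- function(gaze, baseline = c(0, 30)) {
  p <- rowMeans(cbind(gaze$pupil_l, gaze$pupil_r), na.rm = TRUE)
  ok <- gaze$valid == 1L & is.finite(p)
  base <- p[ok & gaze$t >= baseline[1] & gaze$t < baseline[2]]
  if (sum(is.finite(base)) < 1) {
    stopf("empty pupil baseline in [%g, %g)", baseline[1], baseline[2])
  }
  mu <- mean(base)
  s <- sd(base)
  if (!is.finite(s) || s == 0) s <- 1
  data.table(t = gaze$t[ok], pupil = (p[ok] - mu) / s)
}

#' Smooth and decompose EDA into tonic and phasic components
#'
#' A centered moving average (default 0.5 s) removes sensor spikes; the tonic
#' component is a centered moving median (default 4 s) of the smoothed
#' signal; the phasic component is their difference, so tonic + phasic
#' reconstructs the smoothed signal exactly.
#'
#' @param eda data.table with `t`, `eda` (microsiemens)
#' @param smooth_s smoothing-window seconds
#' @param tonic_s tonic moving-median window seconds
#' @return data.table `t`, `smoothed`, `tonic`, `phasic`
#' @export
decompose_eda <- function(eda, smooth_s = 0.5, tonic_s = 4) {
  rate <- 1 / median(diff(eda$t))
  k_s <- max(1L, round(smooth_s * rate))
  if (k_s %% 2 == 0) k_s <- k_s + 1L
  k_t <- max(3L, round(tonic_s * rate))
  if (k_t %% 2 == 0) k_t <- k_t + 1L
  sm <- if (k_s >= 3L && length(eda$eda) >= k_s) {
    as.numeric(zoo::rollmean(zoo::zoo(eda$eda), k_s, fill = "extend"))
  } else {
    eda$eda
  }
  tonic <- if (length(sm) >= k_t) {
    as.numeric(stats::runmed(sm, k_t, endrule = "median"))
  } else {
    rep(median(sm), length(sm))
  }
  data.table(t = eda$t, smoothed = sm, tonic = tonic, phasic = sm - tonic)
}

#' Normalize a series against its leading baseline
#'
#' Subtracts the mean and divides by the SD of the first `baseline_s`
#' seconds. A zero baseline SD divides by 1 and raises the
#' `constant_baseline` attribute.
#'
#' @param t,x time and value vectors
#' @param baseline_s baseline length, seconds
#' @return numeric vector, with attribute `constant_baseline`
#' @export
baseline_normalize <- function(t, x, baseline_s = 30) {
  if (max(t) < baseline_s) {
    stopf(
      "stream spans %.1f s, shorter than the %g s baseline", max(t), baseline_s
    )
  }
  base <- x[t < baseline_s]
  mu <- mean(base, na.rm = TRUE)
  s <- sd(base, na.rm = TRUE)
  flag <- FALSE
  if (!is.finite(s) || s == 0) {
    s <- 1
    flag <- TRUE
  }
  out <- (x - mu) / s
  attr(out, "constant_baseline") <- flag
  out
}

#' Tile an interval with overlapping analysis windows
#'
#' Window starts form an arithmetic sequence at the hop; each window is
#' truncated at the interval end, and a trailing truncated window is kept
#' only when it is strictly longer than half the window length (a trailing
#' window of exactly half the length duplicates the second half of the
#' preceding full window).
#'
#' @param t_start,t_end interval bounds (half-open)
#' @param window_s window length, seconds
#' @param hop_s start-to-start spacing, seconds
#' @return data.table `window` (index), `t_start`, `t_end`, `midpoint`
#' @export
make_windows <- function(t_start, t_end, window_s = 10, hop_s = 5) {
  stopifnot(t_end > t_start)
  starts <- seq(t_start, t_end - 1e-9, by = hop_s)
  ends <- pmin(starts + window_s, t_end)
  len <- ends - starts
  keep <- len >= window_s - 1e-9 | len > window_s / 2 + 1e-9
  starts <- starts[keep]
  ends <- ends[keep]
  data.table(
    window = seq_along(starts), t_start = starts, t_end = ends,
    midpoint = (starts + ends) / 2
  )
}

#' Assign windows to the question phase containing their midpoint
#'
#' @param windows output of [make_windows()]
#' @param segments phase segments (`question`, `phase`, `t_start`, `t_end`)
#' @return `windows` with `question` and `phase` columns (`NA` when the
#'   midpoint falls outside every segment)
#' @export
assign_window_phase <- function(windows, segments) {
  out <- copy(windows)
  out[, `:=`(question = NA_integer_, phase = NA_character_)]
  if (nrow(segments) == 0) {
    return(out)
  }
  for (i in seq_len(nrow(segments))) {
    hit <- out$midpoint >= segments$t_start[i] &
      out$midpoint < segments$t_end[i]
    if (any(hit)) {
      out[hit, `:=`(
        question = segments$question[i], phase = segments$phase[i]
      )]
    }
  }
  out
}
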