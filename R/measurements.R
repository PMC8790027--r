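# Window-level multimodal measurements and the per-phase feature set.
#
# Seven measurements are computed per analysis window: cognitive load
# (windowed mean of baseline-normalized pupil diameter), information
# processing index, saccade velocity, mean heart rate, number of EDA peaks,
# mean phasic EDA and mean tonic EDA; plus the three AOI-transition shares
# per window and the per-question time to first fixation. Measurements are
# MinMax-normalized per measurement (time to first fixation excepted) before
# the inferential stage; each measurement's window series per
# (participant, question, phase) feeds the feature extractor.

MEASUREMENT_NAMES <- c(
  "cognitive_load", "ipi", "saccade_velocity", "mean_hr",
  "eda_peaks", "phasic_eda", "tonic_eda",
  "aoi_transition_q_right", "aoi_transition_q_wrong",
  "aoi_transition_right_wrong", "time_to_first_fixation"
)

# mean of x over half-open windows [starts, ends) on an ordered time grid,
# NA-aware, via cumulative sums
window_mean <- function(t, x, starts, ends) {
  ok <- is.finite(x)
  cs <- cumsum(ifelse(ok, x, 0))
  cn <- cumsum(ok)
  i0 <- findInterval(starts - 1e-9, t) # samples strictly before start
  i1 <- findInterval(ends - 1e-9, t) # samples strictly before end
  n <- cn[pmax(i1, 1)] * (i1 > 0) - cn[pmax(i0, 1)] * (i0 > 0)
  s <- cs[pmax(i1, 1)] * (i1 > 0) - cs[pmax(i0, 1)] * (i0 > 0)
  ifelse(n > 0, s / n, NA_real_)
}

#' Count EDA peaks by prominence
#'
#' Local maxima of the phasic series whose prominence (height above the
#' higher of the two flanking minima, delimited by the nearest higher
#' samples) reaches the threshold.
#'
#' @param x numeric series (phasic EDA, microsiemens)
#' @param prominence minimum prominence (default 0.01 uS)
#' @return nonnegative integer count
#' @export
count_eda_peaks <- function(x, prominence = 0.01) {
  length(find_peaks(x, prominence))
}

#' Locate prominent local maxima
#'
#' @param x numeric series
#' @param prominence minimum prominence
#' @return integer indices of the peaks
#' @export
find_peaks <- function(x, prominence) {
  stopifnot(prominence > 0)
  if (length(x) < 3L) return(integer(0))
  # prominence depends only on the sequence of distinct levels: collapse
  # plateaus first (a peak reports the first index of its plateau)
  r <- rle(x)
  xs <- r$values
  first_idx <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  m <- length(xs)
  if (m < 3L) return(integer(0))
  d <- diff(xs)
  cand <- which(d[-(m - 1L)] > 0 & d[-1] < 0) + 1L
  # a peak less than `prominence` above the global minimum cannot qualify
  cand <- cand[xs[cand] >= min(xs) + prominence]
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    v <- xs[i]
    # walk outward to the nearest higher levels, tracking the minima
    j <- i - 1L
    lmin <- v
    while (j >= 1L && xs[j] <= v) {
      if (xs[j] < lmin) lmin <- xs[j]
      j <- j - 1L
    }
    j <- i + 1L
    rmin <- v
    while (j <= m && xs[j] <= v) {
      if (xs[j] < rmin) rmin <- xs[j]
      j <- j + 1L
    }
    keep[k] <- v - max(lmin, rmin) >= prominence
  }
  first_idx[cand[keep]]
}

#' Information processing index from fixation-saccade pairs
#'
#' Each (fixation, following saccade) pair is global when the fixation is
#' short and the saccade long (both relative to the thresholds), local when
#' the fixation is long and the saccade short, and uncategorized otherwise.
#' IPI = (n_global + 1) / (n_local + 1); the +1 smoothing keeps the ratio
#' finite.
#'
#' @param fix_dur fixation durations of the pairs
#' @param sacc_amp saccade amplitudes of the pairs
#' @param fix_threshold,amp_threshold classification thresholds (> 0),
#'   typically within-participant medians
#' @return the IPI ratio, or `NA` for zero pairs
#' @export
compute_ipi <- function(fix_dur, sacc_amp, fix_threshold, amp_threshold) {
  stopifnot(fix_threshold > 0, amp_threshold > 0)
  if (length(fix_dur) == 0) return(NA_real_)
  global <- fix_dur < fix_threshold & sacc_amp >= amp_threshold
  local <- fix_dur >= fix_threshold & sacc_amp < amp_threshold
  (sum(global) + 1) / (sum(local) + 1)
}

#' AOI-transition shares of a fixation sequence
#'
#' Consecutive fixations landing in two distinct AOIs are counted into three
#' categories: question-right, question-wrong and right-wrong. Fixations
#' outside every AOI break the chain; wrong-wrong transitions are
#' uncategorized and excluded from the denominator.
#'
#' @param aoi character vector of per-fixation AOIs (`"question"`,
#'   `"right"`, `"wrong_*"`, or `NA` outside all AOIs), in time order
#' @return named numeric vector of the three shares in percent (`NA` when no
#'   categorized transition exists)
#' @export
aoi_transition_shares <- function(aoi) {
  shares <- c(q_right = NA_real_, q_wrong = NA_real_, right_wrong = NA_real_)
  cats <- transition_categories(aoi)
  cats <- cats[!is.na(cats)]
  if (length(cats) == 0) return(shares)
  counts <- c(
    q_right = sum(cats == "q_right"),
    q_wrong = sum(cats == "q_wrong"),
    right_wrong = sum(cats == "right_wrong")
  )
  100 * counts / sum(counts)
}

# category of each consecutive-fixation transition; NA for chain breaks
# (outside-AOI fixations), same-AOI dwells and wrong-wrong moves
transition_categories <- function(aoi) {
  if (length(aoi) < 2L) return(character(0))
  from <- aoi_category(aoi[-length(aoi)])
  to <- aoi_category(aoi[-1])
  out <- rep(NA_character_, length(from))
  ok <- !is.na(from) & !is.na(to) & from != to
  pair_q <- ok & (from == "question" | to == "question")
  out[pair_q & (from == "right" | to == "right")] <- "q_right"
  out[pair_q & (from == "wrong" | to == "wrong")] <- "q_wrong"
  out[ok & !pair_q & (from == "right" | to == "right") &
    (from == "wrong" | to == "wrong")] <- "right_wrong"
  out
}

# per-fixation AOI category sequence for one question layout; distinct wrong
# options keep their identity so wrong_i -> wrong_j moves are not dwells
aoi_category_sequence <- function(x, y, layout) {
  classify_aoi(x, y, layout)
}

#' Time to the first question fixation
#'
#' @param onset question onset (seconds)
#' @param fix_t_start fixation start times
#' @param fix_in_question logical: fixation centroid inside the question AOI
#' @return seconds from onset (clamped at 0), `NA` when no question fixation
#' @export
time_to_first_fixation <- function(onset, fix_t_start, fix_in_question) {
  hit <- which(fix_in_question & fix_t_start >= onset - 1e-9)
  if (length(hit) == 0) return(NA_real_)
  max(min(fix_t_start[hit]) - onset, 0)
}

#' Measurements for one analysis window
#'
#' The single-window surface over the batch extractor: computes the seven
#' window measurements from preprocessed inputs restricted to
#' `[window[1], window[2])`.
#'
#' @param events gaze events
#' @param pupil normalized pupil table (`t`, `pupil`)
#' @param phasic data.table `t`, `phasic` (raw, microsiemens), `phasic_n`
#'   (baseline-normalized), `tonic_n`
#' @param hr data.table `t`, `hr_n` (baseline-normalized)
#' @param window `c(t_start, t_end)`
#' @param ipi_thresholds named list `fix`, `amp`
#' @param peak_prominence SCR prominence threshold (uS)
#' @return named list of measurement values (`NA` marks missing)
#' @export
compute_window_measurements <- function(events, pupil, phasic, hr, window,
                                        ipi_thresholds,
                                        peak_prominence = 0.01) {
  t0 <- window[1]
  t1 <- window[2]
  sel_p <- pupil$t >= t0 & pupil$t < t1
  sel_e <- phasic$t >= t0 & phasic$t < t1
  sel_h <- hr$t >= t0 & hr$t < t1
  sac <- events[kind == "saccade" & t_start >= t0 & t_start < t1]
  fix <- events[kind == "fixation" & t_start >= t0 & t_start < t1]
  pairs <- fixation_saccade_pairs(events)
  pairs <- pairs[t_start >= t0 & t_start < t1]
  list(
    cognitive_load = if (any(sel_p)) mean(pupil$pupil[sel_p]) else NA_real_,
    ipi = compute_ipi(
      pairs$fix_dur, pairs$amplitude,
      ipi_thresholds$fix, ipi_thresholds$amp
    ),
    saccade_velocity = if (nrow(sac)) mean(sac$peak_velocity) else NA_real_,
    mean_hr = if (any(sel_h)) mean(hr$hr_n[sel_h]) else NA_real_,
    eda_peaks = count_eda_peaks(phasic$phasic[sel_e], peak_prominence),
    phasic_eda = if (any(sel_e)) mean(phasic$phasic_n[sel_e]) else NA_real_,
    tonic_eda = if (any(sel_e)) mean(phasic$tonic_n[sel_e]) else NA_real_
  )
}

# (fixation, following saccade) pairs: a saccade immediately following a
# fixation in the event stream
fixation_saccade_pairs <- function(events) {
  if (nrow(events) < 2L) {
    return(data.table(
      t_start = numeric(0), fix_dur = numeric(0), amplitude = numeric(0)
    ))
  }
  i <- which(
    events$kind[-nrow(events)] == "fixation" &
      events$kind[-1] == "saccade"
  )
  data.table(
    t_start = events$t_start[i],
    fix_dur = events$t_end[i] - events$t_start[i],
    amplitude = events$amplitude[i + 1L]
  )
}

#' MinMax-normalize values within groups
#'
#' (x - min) / (max - min) per group; constant groups map to 0 and raise the
#' `constant_groups` attribute; missing values stay missing.
#'
#' @param x numeric values
#' @param group grouping vector (same length)
#' @return normalized vector in `[0, 1]`, attribute `constant_groups`
#' @export
minmax_normalize <- function(x, group = rep(1L, length(x))) {
  if (length(x) == 0 || all(is.na(x))) {
    stopf("minmax_normalize: no non-missing values")
  }
  out <- x
  const <- character(0)
  for (g in unique(group)) {
    idx <- which(group == g)
    v <- x[idx]
    if (all(is.na(v))) next
    lo <- min(v, na.rm = TRUE)
    hi <- max(v, na.rm = TRUE)
    if (hi > lo) {
      out[idx] <- (v - lo) / (hi - lo)
    } else {
      out[idx] <- ifelse(is.na(v), NA_real_, 0)
      const <- c(const, as.character(g))
    }
  }
  attr(out, "constant_groups") <- const
  out
}

#' Histogram, autoregressive and GARCH features of a series
#'
#' Mean, median, SD, skewness and excess kurtosis of the values (SD needs
#' n >= 2, skewness/kurtosis n >= 3), AR(2) coefficients for n >= 6 and
#' GARCH(1,1) alpha/beta for n >= 10; shorter series yield explicit `NA`
#' markers, never silent zeros.
#'
#' @param x numeric window series of one measurement in one phase
#' @return named numeric vector of the nine features
#' @export
extract_features <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  out <- c(
    mean = if (n >= 1) mean(x) else NA_real_,
    median = if (n >= 1) median(x) else NA_real_,
    sd = if (n >= 2) sd(x) else NA_real_,
    skewness = if (n >= 3) sample_skewness(x) else NA_real_,
    kurtosis = if (n >= 3) sample_kurtosis(x) else NA_real_
  )
  c(out, fit_ar2(x), fit_garch11(x))
}

# ---------------------------------------------------------------------------
# session-level batch extraction

# preprocess one bundle into the inputs the window measurements need
prepare_session_signals <- function(bundle, config, events = NULL) {
  if (is.null(events)) {
    events <- detect_gaze_events(bundle$gaze, config$velocity_threshold)
  }
  pupil <- normalize_pupil(bundle$gaze, c(0, config$baseline_s))
  dec <- decompose_eda(bundle$eda)
  dec[, `:=`(
    phasic_n = baseline_normalize(t, phasic, config$baseline_s),
    tonic_n = baseline_normalize(t, tonic, config$baseline_s)
  )]
  hr <- copy(bundle$hr)
  hr[, hr_n := baseline_normalize(t, hr, config$baseline_s)]
  fix <- events[kind == "fixation"]
  sac <- events[kind == "saccade"]
  list(
    events = events,
    pupil = pupil,
    eda = dec,
    hr = hr,
    ipi_thresholds = list(
      fix = max(median(fix$t_end - fix$t_start), 1e-6),
      amp = max(median(sac$amplitude, na.rm = TRUE), 1e-6)
    ),
    peak_times = dec$t[find_peaks(dec$phasic, config$peak_prominence)]
  )
}

# long measurement table for one session: one row per
# (question, phase, window, measurement)
session_measurements <- function(bundle, segments, config, signals = NULL) {
  if (is.null(signals)) {
    signals <- prepare_session_signals(bundle, config)
  }
  t_max <- max(bundle$gaze$t)
  win <- make_windows(0, t_max, config$window_s, config$hop_s)
  win <- assign_window_phase(win, segments)
  win <- win[!is.na(phase)]
  if (nrow(win) == 0) {
    return(data.table())
  }

  ev <- signals$events
  m_cl <- window_mean(
    signals$pupil$t, signals$pupil$pupil, win$t_start, win$t_end
  )
  m_hr <- window_mean(signals$hr$t, signals$hr$hr_n, win$t_start, win$t_end)
  m_ph <- window_mean(
    signals$eda$t, signals$eda$phasic_n, win$t_start, win$t_end
  )
  m_to <- window_mean(
    signals$eda$t, signals$eda$tonic_n, win$t_start, win$t_end
  )
  m_pk <- as.numeric(
    findInterval(win$t_end - 1e-9, signals$peak_times) -
      findInterval(win$t_start - 1e-9, signals$peak_times)
  )

  # counts/sums over windows via cumulative sums on sorted event times
  win_sum <- function(times, values = rep(1, length(times))) {
    if (!length(times)) return(rep(0, nrow(win)))
    o <- order(times)
    times <- times[o]
    cs <- c(0, cumsum(values[o]))
    i0 <- findInterval(win$t_start - 1e-9, times)
    i1 <- findInterval(win$t_end - 1e-9, times)
    cs[i1 + 1L] - cs[i0 + 1L]
  }
  sac <- ev[kind == "saccade" & is.finite(peak_velocity)]
  n_sac <- win_sum(sac$t_start)
  m_sv <- ifelse(n_sac > 0, win_sum(sac$t_start, sac$peak_velocity) / n_sac,
    NA_real_
  )

  pairs <- fixation_saccade_pairs(ev)
  thr_f <- signals$ipi_thresholds$fix
  thr_a <- signals$ipi_thresholds$amp
  is_glob <- pairs$fix_dur < thr_f & pairs$amplitude >= thr_a
  is_loc <- pairs$fix_dur >= thr_f & pairs$amplitude < thr_a
  n_pair <- win_sum(pairs$t_start)
  n_glob <- win_sum(pairs$t_start[is_glob])
  n_loc <- win_sum(pairs$t_start[is_loc])
  m_ipi <- ifelse(n_pair > 0, (n_glob + 1) / (n_loc + 1), NA_real_)

  # AOI transitions: consecutive fixations inside one question cycle, each
  # transition stamped with its first fixation's start time
  fixs <- ev[kind == "fixation"]
  tr_time <- numeric(0)
  tr_cat <- character(0)
  for (qi in seq_len(nrow(bundle$log))) {
    entry <- bundle$log[qi]
    sel <- which(fixs$t_start >= entry$onset & fixs$t_start < entry$response)
    if (length(sel) < 2L) next
    layout <- bundle$layouts[[as.character(entry$question_id)]]
    aoi <- aoi_category_sequence(fixs$x[sel], fixs$y[sel], layout)
    cats <- transition_categories(aoi)
    ok <- !is.na(cats)
    tr_time <- c(tr_time, fixs$t_start[sel][-length(sel)][ok])
    tr_cat <- c(tr_cat, cats[ok])
  }
  c_qr <- win_sum(tr_time[tr_cat == "q_right"])
  c_qw <- win_sum(tr_time[tr_cat == "q_wrong"])
  c_rw <- win_sum(tr_time[tr_cat == "right_wrong"])
  tot <- c_qr + c_qw + c_rw
  m_aoi <- cbind(
    ifelse(tot > 0, 100 * c_qr / tot, NA_real_),
    ifelse(tot > 0, 100 * c_qw / tot, NA_real_),
    ifelse(tot > 0, 100 * c_rw / tot, NA_real_)
  )

  qmeta <- unique(segments[, .(question, domain, game, label)])
  base <- data.table(
    participant = bundle$participant_id,
    question = win$question, phase = win$phase, window = win$window
  )
  long <- rbindlist(lapply(
    list(
      cognitive_load = m_cl, ipi = m_ipi, saccade_velocity = m_sv,
      mean_hr = m_hr, eda_peaks = m_pk, phasic_eda = m_ph, tonic_eda = m_to,
      aoi_transition_q_right = m_aoi[, 1],
      aoi_transition_q_wrong = m_aoi[, 2],
      aoi_transition_right_wrong = m_aoi[, 3]
    ),
    function(v) copy(base)[, value := v]
  ), idcol = "measurement")

  # per-question time to first fixation (not windowed)
  in_q <- vapply(seq_len(nrow(bundle$log)), function(i) {
    entry <- bundle$log[i]
    layout <- bundle$layouts[[as.character(entry$question_id)]]
    fx <- fixs[t_start >= entry$onset & t_start < entry$response]
    time_to_first_fixation(
      entry$onset, fx$t_start, point_in_rect(fx$x, fx$y, layout$question)
    )
  }, 0)
  ttff <- data.table(
    measurement = "time_to_first_fixation",
    participant = bundle$participant_id,
    question = bundle$log$question_id, phase = "see_solve",
    window = NA_integer_, value = in_q
  )
  long <- rbindlist(list(long, ttff), use.names = TRUE)
  merge(long, qmeta, by = "question")
}

#' Per-(question, phase) feature vectors from a measurement table
#'
#' For every measurement the ordered window series within each
#' (participant, domain, question, phase) cell is reduced to the nine
#' features of [extract_features()]; the result is one wide row per cell
#' with `<measurement>.<feature>` columns plus the correctness label.
#'
#' @param measurements long measurement table (normalized or raw)
#' @param measurement_set measurements to featurize
#' @return wide data.table of feature vectors
#' @export
feature_table <- function(measurements,
                          measurement_set = supported_measurements()) {
  m <- measurements[
    measurement %in% measurement_set & !is.na(window)
  ]
  if (nrow(m) == 0) {
    return(data.table())
  }
  setorder(m, participant, domain, question, phase, measurement, window)
  feats <- m[, as.list(extract_features(value)),
    by = .(participant, domain, question, phase, measurement, label)
  ]
  long <- data.table::melt(
    feats,
    id.vars = c(
      "participant", "domain", "question", "phase", "measurement", "label"
    ),
    variable.name = "feature", value.name = "value"
  )
  long[, feature := paste(measurement, feature, sep = ".")]
  wide <- data.table::dcast(
    long, participant + domain + question + phase + label ~ feature,
    value.var = "value"
  )
  wide
}
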