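# See-Solve / Move / Respond segmentation of question cycles.
#
# See-Solve starts at the first fixation on the question AOI at or after the
# logged question onset; Move starts at the first skeletal frame after that
# whose whole-body displacement exceeds an individual threshold; Respond
# spans the logged selection-to-response interval. The three segments are
# contiguous and half-open, partitioning [see_solve_start, response).

#' Per-frame whole-body displacement
#'
#' Sum over the 25 joints of the Euclidean distance between consecutive
#' frames; the first frame gets displacement 0.
#'
#' @param skeleton data.table with `t` and 75 coordinate columns
#' @return data.table `t`, `displacement` (meters)
#' @export
skeletal_displacement <- function(skeleton) {
  coord <- as.matrix(skeleton[, setdiff(names(skeleton), "t"), with = FALSE])
  n <- nrow(coord)
  if (n < 2L) {
    return(data.table(t = skeleton$t, displacement = rep(0, n)))
  }
  d <- coord[-1L, , drop = FALSE] - coord[-n, , drop = FALSE]
  per_joint <- sqrt(
    d[, seq(1, 73, 3), drop = FALSE]^2 +
      d[, seq(2, 74, 3), drop = FALSE]^2 +
      d[, seq(3, 75, 3), drop = FALSE]^2
  )
  data.table(t = skeleton$t, displacement = c(0, rowSums(per_joint)))
}

#' Individual movement threshold
#'
#' Mean plus `k` SDs of the baseline per-frame displacements. Requires at
#' least three frames; callers fall back to a participant-level baseline
#' when a cycle offers fewer.
#'
#' @param displacements numeric vector of per-frame displacements
#' @param k SD multiplier (default 2)
#' @return strictly nonnegative threshold
#' @export
movement_threshold <- function(displacements, k = 2) {
  displacements <- displacements[is.finite(displacements)]
  if (length(displacements) < 3L) {
    stopf(
      "movement threshold needs >= 3 baseline frames, got %d",
      length(displacements)
    )
  }
  mean(displacements) + k * sd(displacements)
}

#' Segment one question cycle into its three phases
#'
#' @param events gaze events from [detect_gaze_events()]
#' @param displacement per-frame displacement table from
#'   [skeletal_displacement()]
#' @param log_entry list/row with `onset`, `selection`, `response`
#' @param layout AOI layout of the question
#' @param k movement-threshold SD multiplier
#' @param participant_threshold fallback threshold when a cycle has fewer
#'   than three pre-movement frames (`NULL` = none available)
#' @return data.table of three `PhaseSegment` rows (`phase`, `t_start`,
#'   `t_end`) or `NULL` when the cycle is unusable (no fixation ever lands
#'   on the question AOI); a collapsed Move segment carries attribute
#'   `move_collapsed = TRUE`
#' @export
segment_cycle <- function(events, displacement, log_entry, layout,
                          k = 2, participant_threshold = NULL) {
  onset <- log_entry$onset
  selection <- log_entry$selection
  response <- log_entry$response
  fix <- events[
    kind == "fixation" & t_start >= onset - 1e-9 & t_start < response
  ]
  if (nrow(fix) == 0) {
    return(NULL)
  }
  in_q <- point_in_rect(fix$x, fix$y, layout$question)
  if (!any(in_q)) {
    return(NULL)
  }
  ss_start <- max(fix$t_start[which(in_q)[1]], onset)

  # expanding-baseline movement detection between See-Solve start and the
  # logged selection: frame j triggers when it exceeds mean + k SD of the
  # frames observed since ss_start; the participant-level rest threshold is
  # a floor (short early baselines underestimate the idle spread) and the
  # fallback when a cycle offers fewer than three baseline frames
  cand <- displacement[t > ss_start & t <= selection]
  move_start <- NA_real_
  collapsed <- FALSE
  if (nrow(cand) > 0) {
    for (j in seq_len(nrow(cand))) {
      thr <- if (j >= 4L) {
        max(
          movement_threshold(cand$displacement[seq_len(j - 1L)], k),
          participant_threshold %||% -Inf
        )
      } else {
        participant_threshold
      }
      if (!is.null(thr) && !is.na(thr) && cand$displacement[j] > thr) {
        move_start <- cand$t[j]
        break
      }
    }
  }
  if (is.na(move_start) || move_start > selection) {
    move_start <- selection # collapsed zero-length move
    collapsed <- TRUE
  }
  move_start <- max(move_start, ss_start)

  out <- data.table(
    phase = c("see_solve", "move", "respond"),
    t_start = c(ss_start, move_start, selection),
    t_end = c(move_start, selection, response)
  )
  attr(out, "move_collapsed") <- collapsed
  out
}

#' Segment every question cycle of a session
#'
#' Computes gaze events and skeletal displacement once, derives the
#' participant-level fallback movement threshold from the rest-period frames,
#' and segments each logged question. Unusable cycles (no question-AOI
#' fixation) are excluded and counted.
#'
#' @param bundle a `session_bundle`
#' @param config a [run_config()]
#' @param events optional precomputed gaze events
#' @return data.table of segments with `participant`, `domain`, `game`,
#'   `question`, `phase`, `t_start`, `t_end`; attributes `n_unusable` and
#'   `n_collapsed`
#' @export
segment_session <- function(bundle, config = run_config(), events = NULL) {
  if (is.null(events)) {
    events <- detect_gaze_events(bundle$gaze, config$velocity_threshold)
  }
  disp <- skeletal_displacement(bundle$skeleton)
  rest <- disp[t > 0 & t < config$baseline_s]
  part_thr <- if (nrow(rest) >= 3L) {
    movement_threshold(rest$displacement, config$movement_k)
  } else {
    NULL
  }
  segs <- vector("list", nrow(bundle$log))
  n_unusable <- 0L
  n_collapsed <- 0L
  for (i in seq_len(nrow(bundle$log))) {
    entry <- bundle$log[i]
    layout <- bundle$layouts[[as.character(entry$question_id)]]
    s <- segment_cycle(
      events, disp, entry, layout,
      k = config$movement_k, participant_threshold = part_thr
    )
    if (is.null(s)) {
      n_unusable <- n_unusable + 1L
      next
    }
    if (isTRUE(attr(s, "move_collapsed"))) n_collapsed <- n_collapsed + 1L
    s[, `:=`(
      participant = bundle$participant_id, domain = entry$domain,
      game = entry$game, question = entry$question_id,
      label = ifelse(entry$correct, "right", "wrong")
    )]
    segs[[i]] <- s
  }
  out <- rbindlist(segs)
  attr(out, "n_unusable") <- n_unusable
  attr(out, "n_collapsed") <- n_collapsed
  out
}
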