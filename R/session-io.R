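# On-disk session formats.
#
# A session directory holds five plain-text files:
#   gaze.csv      t,x,y,pupil_l,pupil_r,valid   (seconds; [0,1] screen units)
#   EDA.csv       Empatica-E4 dialect: row 1 = UTC start epoch,
#                 row 2 = sampling rate (Hz), then one value (uS) per row
#   HR.csv        same dialect, one value (bpm) per row
#   skeleton.csv  t plus 75 coordinate columns j01_x .. j25_z (meters)
#   log.json      one object per question: onset/selection/response times,
#                 chosen option, correctness, AOI layout
#
# All timestamps are seconds from a shared session t = 0; intervals are
# half-open [start, end) throughout the package.

E4_EPOCH <- 1600000000 # fixed synthetic recording start (UTC epoch seconds)

#' Pipeline run configuration
#'
#' @param window_s analysis window length, seconds
#' @param hop_s window hop (window minus overlap), seconds; must be <= window
#' @param baseline_s leading baseline used for EDA/HR/pupil normalization
#' @param velocity_threshold I-VT saccade threshold, screen units per second
#' @param peak_prominence minimum SCR prominence, microsiemens
#' @param alpha significance level for the inferential tests
#' @param top_fraction top share of important features for the predictive
#'   carry-forward classification
#' @param movement_k multiplier on the baseline displacement SD for the
#'   individual movement threshold
#' @param pseudo_rule which inferential Pseudo-CFE rule to apply: the
#'   worked-example reading (`"examples"`, default — the Move>Respond
#'   ordering is the pseudo-breaking condition) or the literal decision-text
#'   reading (`"text"` — consistent affinity is)
#' @param seed integer seed for all stochastic pipeline stages
#' @return a `run_config` list
#' @export
run_config <- function(window_s = 10, hop_s = 5, baseline_s = 30,
                       velocity_threshold = 1.0, peak_prominence = 0.01,
                       alpha = 0.05, top_fraction = 0.10, movement_k = 2,
                       pseudo_rule = c("examples", "text"), seed = 1L) {
  stopifnot(
    hop_s <= window_s, hop_s > 0, window_s > 0, baseline_s > 0,
    alpha > 0, alpha < 1, top_fraction > 0, top_fraction <= 1,
    velocity_threshold > 0, peak_prominence > 0, movement_k >= 0
  )
  structure(
    list(
      window_s = window_s, hop_s = hop_s, baseline_s = baseline_s,
      velocity_threshold = velocity_threshold,
      peak_prominence = peak_prominence, alpha = alpha,
      top_fraction = top_fraction, movement_k = movement_k,
      pseudo_rule = match.arg(pseudo_rule), seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

fmt_num <- function(x) formatC(x, format = "g", digits = 10)

write_e4_csv <- function(values, rate, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(fmt_num(E4_EPOCH), fmt_num(rate), fmt_num(values)), con)
}

read_e4_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) {
    stopf("%s: truncated Empatica file (%d lines)", path, length(lines))
  }
  start <- suppressWarnings(as.numeric(lines[1]))
  rate <- suppressWarnings(as.numeric(lines[2]))
  values <- suppressWarnings(as.numeric(lines[-(1:2)]))
  if (!is.finite(start) || !is.finite(rate) || rate <= 0) {
    stopf("%s: line 1-2 must hold start epoch and a positive rate", path)
  }
  if (anyNA(values)) {
    stopf("%s: non-numeric sample at line %d", path, which(is.na(values))[1] + 2L)
  }
  list(start = start, rate = rate, values = values)
}

check_columns <- function(dt, cols, path) {
  missing <- setdiff(cols, names(dt))
  if (length(missing)) {
    stopf("%s: missing column(s) %s", path, paste(missing, collapse = ", "))
  }
}

check_monotone <- function(t, path) {
  bad <- which(diff(t) <= 0)
  if (length(bad)) {
    stopf("%s: timestamps not strictly increasing at line %d", path, bad[1] + 1L)
  }
}

layout_to_list <- function(layout) {
  list(
    question = unname(layout$question),
    options = lapply(layout$options, function(o) {
      list(rect = unname(o$rect), correct = o$correct)
    })
  )
}

layout_from_list <- function(lst) {
  list(
    question = as.numeric(unlist(lst$question)),
    options = lapply(lst$options, function(o) {
      list(rect = as.numeric(unlist(o$rect)), correct = isTRUE(unlist(o$correct)))
    })
  )
}

#' Write a session bundle to a directory
#'
#' @param bundle a `session_bundle`
#' @param dir target directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_session <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- bundle$gaze
  gaze_out <- data.frame(
    t = fmt_num(g$t), x = fmt_num(g$x), y = fmt_num(g$y),
    pupil_l = ifelse(is.na(g$pupil_l), "", fmt_num(g$pupil_l)),
    pupil_r = ifelse(is.na(g$pupil_r), "", fmt_num(g$pupil_r)),
    valid = g$valid
  )
  utils::write.csv(gaze_out, file.path(dir, "gaze.csv"),
    row.names = FALSE, quote = FALSE
  )
  eda_rate <- 1 / median(diff(bundle$eda$t))
  hr_rate <- 1 / median(diff(bundle$hr$t))
  write_e4_csv(bundle$eda$eda, round(eda_rate, 6), file.path(dir, "EDA.csv"))
  write_e4_csv(bundle$hr$hr, round(hr_rate, 6), file.path(dir, "HR.csv"))
  sk <- as.data.frame(bundle$skeleton)
  sk[] <- lapply(sk, fmt_num)
  utils::write.csv(sk, file.path(dir, "skeleton.csv"),
    row.names = FALSE, quote = FALSE
  )
  log_list <- lapply(seq_len(nrow(bundle$log)), function(i) {
    row <- bundle$log[i]
    c(
      as.list(row),
      list(layout = layout_to_list(bundle$layouts[[as.character(row$question_id)]]))
    )
  })
  jsonlite::write_json(
    list(participant_id = bundle$participant_id, questions = log_list),
    file.path(dir, "log.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' Wristband files are interpreted in the Empatica-E4 dialect and re-based to
#' the shared session t = 0. Readers validate required columns, strictly
#' increasing timestamps and file integrity, and fail rather than return
#' partial streams.
#'
#' @param dir session directory written by [write_session()]
#' @return a `session_bundle`
#' @export
read_session <- function(dir) {
  gaze_path <- file.path(dir, "gaze.csv")
  gaze <- as.data.table(utils::read.csv(gaze_path))
  check_columns(gaze, c("t", "x", "y", "pupil_l", "pupil_r", "valid"), gaze_path)
  check_monotone(gaze$t, gaze_path)

  eda_raw <- read_e4_csv(file.path(dir, "EDA.csv"))
  hr_raw <- read_e4_csv(file.path(dir, "HR.csv"))
  eda <- data.table(
    t = (seq_along(eda_raw$values) - 1) / eda_raw$rate,
    eda = eda_raw$values
  )
  hr <- data.table(
    t = (seq_along(hr_raw$values) - 1) / hr_raw$rate,
    hr = hr_raw$values
  )

  sk_path <- file.path(dir, "skeleton.csv")
  skeleton <- as.data.table(utils::read.csv(sk_path))
  coord_cols <- setdiff(names(skeleton), "t")
  if (!"t" %in% names(skeleton) || length(coord_cols) != 75L) {
    stopf("%s: expected t plus 75 coordinate columns", sk_path)
  }
  check_monotone(skeleton$t, sk_path)

  log_raw <- jsonlite::read_json(file.path(dir, "log.json"))
  qs <- log_raw$questions
  log_dt <- rbindlist(lapply(qs, function(q) {
    data.table(
      question_id = as.integer(q$question_id), domain = q$domain,
      game = as.integer(q$game), onset = as.numeric(q$onset),
      selection = as.numeric(q$selection), response = as.numeric(q$response),
      chosen = as.integer(q$chosen), correct = isTRUE(q$correct)
    )
  }))
  if (nrow(log_dt)) {
    bad <- log_dt[
      !(onset < selection & selection < response)
    ]
    if (nrow(bad)) {
      stopf(
        "%s: question %d violates onset < selection < response",
        file.path(dir, "log.json"), bad$question_id[1]
      )
    }
  }
  layouts <- lapply(qs, function(q) layout_from_list(q$layout))
  names(layouts) <- as.character(log_dt$question_id)

  structure(
    list(
      participant_id = log_raw$participant_id,
      gaze = gaze, eda = eda, hr = hr, skeleton = skeleton,
      log = log_dt, layouts = layouts,
      ground_truth = NULL
    ),
    class = "session_bundle"
  )
}

#' Write a cohort of session bundles
#'
#' One subdirectory per participant under `dir`.
#'
#' @param cohort list of `session_bundle` objects
#' @param dir target directory
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  for (b in cohort) write_session(b, file.path(dir, b$participant_id))
  invisible(dir)
}

#' Read a cohort of session bundles
#'
#' @param dir directory holding one session subdirectory per participant
#' @return list of `session_bundle` objects
#' @export
read_cohort <- function(dir) {
  subdirs <- sort(list.dirs(dir, recursive = FALSE))
  lapply(subdirs, read_session)
}

write_tsv <- function(dt, path, digits = 4) {
  dt <- as.data.frame(dt)
  num <- vapply(dt, is.numeric, TRUE)
  dt[num] <- lapply(dt[num], function(x) round(x, digits))
  utils::write.table(dt, path,
    sep = "\t", row.names = FALSE, quote = FALSE, na = "-"
  )
  invisible(path)
}

#' Write the pipeline report files
#'
#' Emits the effect-size table (measurement by phase, with CFE class), the
#' feature-rank table, the prediction-metrics table as TSV, and the ordered
#' feedback plan as JSON. Empty result components yield headers-only files.
#'
#' @param results list with any of `effects` (effect table with cfe class),
#'   `ranks` (importance rank table), `metrics` (prediction metrics),
#'   `plan` (feedback plan)
#' @param dir output directory
#' @return character vector of written paths, invisibly
#' @export
write_reports <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  empty <- function(cols) {
    setNames(
      as.data.table(lapply(cols, function(x) numeric(0))), cols
    )
  }
  eff <- results$effects %||% empty(c(
    "domain", "measurement", "es_see_solve", "es_move", "es_respond", "cfe"
  ))
  paths["effects"] <- write_tsv(eff, file.path(dir, "effect_table.tsv"))
  ranks <- results$ranks %||% empty(c(
    "domain", "feature", "rank_see_solve", "rank_move", "rank_respond", "cfe"
  ))
  paths["ranks"] <- write_tsv(ranks, file.path(dir, "rank_table.tsv"))
  metrics <- results$metrics %||% empty(c(
    "domain", "phase", "precision", "recall", "f1"
  ))
  paths["metrics"] <- write_tsv(metrics, file.path(dir, "prediction_metrics.tsv"))
  plan <- results$plan %||% data.table(
    priority = integer(0), measurement = character(0)
  )
  jsonlite::write_json(plan, file.path(dir, "feedback_plan.json"),
    auto_unbox = FALSE, digits = NA, dataframe = "rows"
  )
  paths["plan"] <- file.path(dir, "feedback_plan.json")
  invisible(paths)
}
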