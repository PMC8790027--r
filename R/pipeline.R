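# End-to-end driver: segmentation -> preprocessing -> measurements ->
# inferential CFE (+ optional predictive CFE) -> feedback plan -> reports.

#' Run the full carry-forward analysis over a cohort
#'
#' @param cohort list of `session_bundle` objects (e.g. from
#'   [generate_cohort()] or [read_cohort()])
#' @param config a [run_config()]
#' @param measurement_set measurements to analyze
#' @param include_predictive run the ensemble/importance stage (the
#'   computationally heavy part)
#' @param out_dir when non-NULL, write the report files there
#' @return list with `segments`, `measurements` (MinMax-normalized long
#'   table), `effects` (per-domain effect tables), `cfe_inferential`,
#'   `prediction` (per domain: metrics + rank tables + predictive CFE, when
#'   requested), `plans` (per-domain feedback plans), `report_tables`, and
#'   bookkeeping counts
#' @export
run_cfe_pipeline <- function(cohort, config = run_config(),
                             measurement_set = supported_measurements(),
                             include_predictive = TRUE,
                             out_dir = NULL) {
  seg_list <- list()
  meas_list <- list()
  n_unusable <- 0L
  for (b in cohort) {
    events <- detect_gaze_events(b$gaze, config$velocity_threshold)
    segs <- segment_session(b, config, events = events)
    n_unusable <- n_unusable + attr(segs, "n_unusable")
    if (nrow(segs) == 0) next
    signals <- prepare_session_signals(b, config, events = events)
    meas <- session_measurements(b, segs, config, signals = signals)
    seg_list[[b$participant_id]] <- segs
    meas_list[[b$participant_id]] <- meas
  }
  segments <- rbindlist(seg_list)
  measurements <- rbindlist(meas_list)
  if (nrow(measurements) == 0) stopf("no usable cycles in the cohort")

  # MinMax normalization per (domain, measurement); the time to first
  # fixation stays on its natural seconds scale
  measurements[, norm_value := value]
  mm <- measurements$measurement != "time_to_first_fixation"
  measurements[mm == TRUE, norm_value := minmax_normalize(
    value, paste(domain, measurement)
  )]

  domains <- sort(unique(measurements$domain))
  effects <- list()
  cfe_inf <- list()
  plans <- list()
  prediction <- list()
  for (d in domains) {
    md <- measurements[domain == d]
    md_norm <- copy(md)[, value := norm_value]
    eff <- phase_effect_table(md_norm, config$alpha, measurement_set)
    cfe <- cfe_inferential_table(eff, config$pseudo_rule)
    effects[[d]] <- eff
    cfe_inf[[d]] <- cfe
    plans[[d]] <- prioritize(cfe, eff)

    if (include_predictive) {
      feats <- feature_table(md_norm, measurement_set)
      phase_out <- list()
      for (ph in c("see_solve", "move", "respond")) {
        fp <- feats[phase == ph]
        if (nrow(fp) < 6 || length(unique(fp$participant)) < 3) next
        po <- tryCatch(
          run_predictive_phase(
            fp,
            seed = derive_seed(
              config$seed, match(d, domains) * 10 +
                match(ph, c("see_solve", "move", "respond"))
            )
          ),
          error = function(e) {
            warning(sprintf(
              "predictive stage skipped for %s/%s: %s", d, ph,
              conditionMessage(e)
            ), call. = FALSE)
            NULL
          }
        )
        if (!is.null(po)) phase_out[[ph]] <- po
      }
      if (length(phase_out) == 3) {
        rank_tables <- lapply(phase_out, function(po) {
          rank_feature_importance(po$importance, config$top_fraction)
        })
        prediction[[d]] <- list(
          phases = phase_out,
          rank_tables = rank_tables,
          cfe = cfe_predictive_table(rank_tables)
        )
      } else {
        prediction[[d]] <- list(phases = phase_out)
      }
    }
  }

  report <- build_report_tables(domains, effects, cfe_inf, prediction, plans)
  if (!is.null(out_dir)) {
    write_reports(report, out_dir)
  }

  list(
    segments = segments, measurements = measurements,
    effects = effects, cfe_inferential = cfe_inf,
    prediction = if (include_predictive) prediction else NULL,
    plans = plans, report_tables = report,
    n_unusable = n_unusable
  )
}

# assemble the Table-2/3/4-shaped report frames
build_report_tables <- function(domains, effects, cfe_inf, prediction,
                                plans) {
  eff_rows <- lapply(domains, function(d) {
    wide <- data.table::dcast(
      effects[[d]][, .(measurement, phase, effect_size)],
      measurement ~ phase,
      value.var = "effect_size"
    )
    setnames(
      wide, c("see_solve", "move", "respond"),
      c("es_see_solve", "es_move", "es_respond"),
      skip_absent = TRUE
    )
    wide[, domain := d]
    merge(wide, cfe_inf[[d]][, .(measurement, cfe = cfe_class)],
      by = "measurement"
    )
  })
  eff_tab <- rbindlist(eff_rows, fill = TRUE)

  metric_rows <- list()
  rank_rows <- list()
  for (d in names(prediction)) {
    pr <- prediction[[d]]
    for (ph in names(pr$phases)) {
      m <- pr$phases[[ph]]$metrics
      metric_rows[[paste(d, ph)]] <- data.table(
        domain = d, phase = ph,
        precision = m$precision, recall = m$recall, f1 = m$f1
      )
    }
    if (!is.null(pr$cfe)) {
      rk <- copy(pr$cfe)[in_top_any == TRUE]
      rk[, domain := d]
      rank_rows[[d]] <- rk[, .(
        domain, feature, rank_see_solve, rank_move, rank_respond,
        cfe = cfe_class
      )]
    }
  }
  plan_rows <- lapply(names(plans), function(d) {
    p <- copy(plans[[d]])
    p[, domain := d]
    p
  })
  list(
    effects = if (nrow(eff_tab)) eff_tab[, .(
      domain, measurement, es_see_solve, es_move, es_respond, cfe
    )] else NULL,
    metrics = if (length(metric_rows)) rbindlist(metric_rows) else NULL,
    ranks = if (length(rank_rows)) rbindlist(rank_rows) else NULL,
    plan = if (length(plan_rows)) rbindlist(plan_rows) else NULL
  )
}
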