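# Shared fixtures, built in code at test time.

library(data.table)

# gaze sample table for a sequence of fixation dwells:
# targets = list(c(x, y, duration_s)); 50 Hz, jitter optional
make_gaze_dwells <- function(targets, jitter = 0, rate = 50, pupil = 3) {
  rows <- list()
  t0 <- 0
  for (tg in targets) {
    n <- round(tg[3] * rate)
    rows[[length(rows) + 1L]] <- data.table(
      t = t0 + (seq_len(n) - 1) / rate,
      x = tg[1] + rnorm(n, 0, jitter),
      y = tg[2] + rnorm(n, 0, jitter)
    )
    t0 <- t0 + n / rate
  }
  g <- rbindlist(rows)
  g[, `:=`(pupil_l = pupil, pupil_r = pupil, valid = 1L)]
  g
}

# layout with the correct option in slot `correct_slot`
make_test_layout <- function(correct_slot = 1L) {
  slots <- list(
    c(0.05, 0.08, 0.30, 0.28),
    c(0.375, 0.08, 0.625, 0.28),
    c(0.70, 0.08, 0.95, 0.28)
  )
  list(
    question = c(0.15, 0.72, 0.85, 0.92),
    options = lapply(seq_len(3), function(i) {
      list(rect = slots[[i]], correct = i == correct_slot)
    })
  )
}

# cache expensive cohorts across test files within one run
.fixture_env <- new.env(parent = emptyenv())

cached_cohort <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# small feature matrix with two informative columns and noise columns
make_blob_features <- function(n_per_class = 40, n_noise = 6, sep = 3,
                               seed = 1) {
  set.seed(seed)
  x_info <- rbind(
    matrix(rnorm(n_per_class * 2), ncol = 2),
    matrix(rnorm(n_per_class * 2, mean = sep), ncol = 2)
  )
  x <- cbind(x_info, matrix(rnorm(2 * n_per_class * n_noise), ncol = n_noise))
  colnames(x) <- c("info1", "info2", paste0("noise", seq_len(n_noise)))
  y <- rep(c("wrong", "right"), each = n_per_class)
  list(x = x, y = y)
}
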