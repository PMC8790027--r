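# Window measurements: peak counting, IPI, AOI transitions, time to first
# fixation, MinMax normalization and the feature extractor.

test_that("peak counting by prominence matches constructions", {
  expect_equal(count_eda_peaks(rep(0, 500), 0.01), 0L)
  t <- seq(0, 30, by = 1 / 64)
  three <- 0.05 * (
    exp(-(t - 5)^2 / 0.5) + exp(-(t - 15)^2 / 0.5) + exp(-(t - 25)^2 / 0.5)
  )
  expect_equal(count_eda_peaks(three, 0.01), 3L)
  # sub-prominence ripples do not count
  expect_equal(count_eda_peaks(three + 0.004 * sin(40 * t), 0.06), 0L)
})

test_that("raising prominence never increases the peak count", {
  for (s in 1:20) {
    set.seed(s)
    x <- cumsum(rnorm(800, 0, 0.01))
    counts <- sapply(
      c(0.005, 0.01, 0.02, 0.05, 0.1),
      function(p) count_eda_peaks(x, p)
    )
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("prominent peaks agree with a brute-force prominence oracle", {
  brute <- function(x, prom) {
    n <- length(x)
    hits <- integer(0)
    for (i in 2:(n - 1)) {
      if (!(x[i] > x[i - 1] && x[i] >= x[i + 1])) next
      if (i > 2 && x[i] == x[i - 1]) next
      hl <- which(x[seq_len(i - 1)] > x[i])
      lo <- if (length(hl)) max(hl) else 1L
      hr <- which(x[(i + 1):n] > x[i])
      hi <- if (length(hr)) i + min(hr) else n
      if (x[i] - max(min(x[lo:i]), min(x[i:hi])) >= prom) {
        hits <- c(hits, i)
      }
    }
    hits
  }
  for (s in 1:5) {
    set.seed(s)
    x <- cumsum(rnorm(300, 0, 0.02))
    expect_identical(find_peaks(x, 0.03), brute(x, 0.03))
  }
})

test_that("IPI follows the smoothed global/local ratio", {
  # all four pairs local: (0 + 1) / (4 + 1) = 0.2
  expect_equal(
    compute_ipi(rep(0.6, 4), rep(0.05, 4), 0.3, 0.2), 0.2
  )
  # equal global and local counts give 1
  expect_equal(
    compute_ipi(c(0.1, 0.1, 0.6, 0.6), c(0.5, 0.5, 0.05, 0.05), 0.3, 0.2), 1
  )
  expect_true(is.na(compute_ipi(numeric(0), numeric(0), 0.3, 0.2)))
  # threshold sweep equals brute-force pair classification
  set.seed(7)
  fd <- runif(50, 0.05, 1)
  sa <- runif(50, 0.01, 0.8)
  for (ft in c(0.2, 0.4, 0.6)) {
    for (at in c(0.1, 0.3, 0.5)) {
      ng <- sum(fd < ft & sa >= at)
      nl <- sum(fd >= ft & sa < at)
      expect_equal(compute_ipi(fd, sa, ft, at), (ng + 1) / (nl + 1))
    }
  }
})

test_that("AOI transition shares follow the three-category rule", {
  s1 <- aoi_transition_shares(c("question", "right", "question"))
  expect_equal(unname(s1), c(100, 0, 0))
  # wrong-wrong moves are uncategorized and excluded from the denominator
  s2 <- aoi_transition_shares(c("question", "wrong_1", "wrong_2", "right"))
  expect_equal(unname(s2), c(0, 50, 50))
  # outside-AOI fixations break chains
  s3 <- aoi_transition_shares(c("question", NA, "right"))
  expect_true(all(is.na(s3)))
  # random sequences equal a transition-matrix oracle
  set.seed(11)
  pool <- c("question", "right", "wrong_1", "wrong_2", NA)
  for (rep in 1:20) {
    seqs <- sample(pool, 30, replace = TRUE)
    got <- aoi_transition_shares(seqs)
    cat_map <- function(a) ifelse(startsWith(a, "wrong"), "wrong", a)
    counts <- c(q_right = 0, q_wrong = 0, right_wrong = 0)
    for (i in seq_len(length(seqs) - 1)) {
      a <- seqs[i]
      b <- seqs[i + 1]
      if (is.na(a) || is.na(b)) next
      ca <- cat_map(a)
      cb <- cat_map(b)
      if (ca == cb) next
      key <- paste(sort(c(ca, cb)), collapse = "_")
      k <- switch(key,
        question_right = "q_right", question_wrong = "q_wrong",
        right_wrong = "right_wrong", NA
      )
      if (!is.na(k)) counts[k] <- counts[k] + 1
    }
    if (sum(counts) == 0) {
      expect_true(all(is.na(got)))
    } else {
      expect_equal(unname(got), unname(100 * counts / sum(counts)))
    }
  }
})

test_that("time to first fixation scans the fixation list", {
  expect_equal(time_to_first_fixation(10, c(10, 12), c(TRUE, TRUE)), 0)
  expect_equal(time_to_first_fixation(10, c(9, 11.4), c(TRUE, TRUE)), 1.4)
  expect_true(is.na(time_to_first_fixation(10, c(11, 12), c(FALSE, FALSE))))
  # equals a brute-force min over qualifying fixations
  set.seed(13)
  for (rep in 1:10) {
    ts <- sort(runif(20, 0, 30))
    inq <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    onset <- runif(1, 0, 20)
    got <- time_to_first_fixation(onset, ts, inq)
    cand <- ts[inq & ts >= onset]
    if (length(cand) == 0) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, min(cand) - onset)
    }
  }
})

test_that("MinMax normalization maps groups to [0, 1]", {
  expect_equal(
    as.numeric(minmax_normalize(c(1, 3, 5))), c(0, 0.5, 1)
  )
  z <- minmax_normalize(c(2, 2))
  expect_equal(as.numeric(z), c(0, 0))
  expect_length(attr(z, "constant_groups"), 1L)
  # idempotence
  x <- c(0.3, 0.9, 0.1, NA, 0.7)
  once <- as.numeric(minmax_normalize(x))
  twice <- as.numeric(minmax_normalize(once))
  expect_equal(once, twice)
  expect_true(is.na(once[4]))
  # per-group independence
  g <- c(1, 1, 2, 2)
  z2 <- as.numeric(minmax_normalize(c(0, 10, 100, 200), g))
  expect_equal(z2, c(0, 1, 0, 1))
  expect_error(minmax_normalize(c(NA_real_, NA_real_)), "non-missing")
})

test_that("feature extractor marks short series missing, never zero", {
  f <- extract_features(c(2, 2, 2, 2))
  expect_equal(unname(f["mean"]), 2)
  expect_equal(unname(f["sd"]), 0)
  expect_true(is.na(f["skewness"])) # zero variance
  expect_true(is.na(f["ar1"])) # n < 6
  expect_true(is.na(f["garch_alpha"]))
  f2 <- extract_features(5)
  expect_equal(unname(f2["mean"]), 5)
  expect_true(is.na(f2["sd"]))
  f3 <- extract_features(c(1, 2, 4, 8, 3))
  expect_false(is.na(f3["skewness"]))
  expect_true(is.na(f3["ar1"]))
})

test_that("AR coefficients recover a known AR(1) process", {
  est <- sapply(1:6, function(s) {
    set.seed(16 + s)
    unname(fit_ar2(as.numeric(arima.sim(list(ar = 0.6), n = 200)))["ar1"])
  })
  expect_true(all(abs(est - 0.6) < 0.2))
  expect_lt(abs(mean(est) - 0.6), 0.1)
})

sim_garch11 <- function(seed, n, omega = 0.05, alpha = 0.1, beta = 0.8) {
  set.seed(seed)
  h <- e <- numeric(n)
  h[1] <- omega / (1 - alpha - beta)
  e[1] <- rnorm(1, 0, sqrt(h[1]))
  for (i in 2:n) {
    h[i] <- omega + alpha * e[i - 1]^2 + beta * h[i - 1]
    e[i] <- rnorm(1, 0, sqrt(h[i]))
  }
  e
}

test_that("GARCH estimates recover a known GARCH(1,1) process", {
  # the per-sample sampling spread of beta at n = 500 is wide; recovery is
  # asserted on the seed average plus a tighter large-n single run
  est <- t(sapply(1:8, function(s) fit_garch11(sim_garch11(s, 500))))
  expect_lt(abs(mean(est[, "garch_alpha"]) - 0.1), 0.1)
  expect_lt(abs(mean(est[, "garch_beta"]) - 0.8), 0.15)
  big <- fit_garch11(sim_garch11(2, 3000))
  expect_lt(abs(big[["garch_alpha"]] - 0.1), 0.1)
  expect_lt(abs(big[["garch_beta"]] - 0.8), 0.15)
})

test_that("window measurements aggregate the preprocessed inputs", {
  # pupil at baseline across the window -> cognitive load 0;
  # HR {60, 62, 64} -> mean 62 before normalization
  events <- data.table(
    kind = c("fixation", "saccade", "fixation"),
    t_start = c(0, 1, 1.1), t_end = c(1, 1.1, 2),
    x = c(0.5, NA, 0.52), y = c(0.8, NA, 0.82),
    amplitude = c(NA, 0.2, NA), peak_velocity = c(NA, 4, NA)
  )
  pupil <- data.table(t = seq(0, 2, 0.02), pupil = 0)
  phasic <- data.table(
    t = seq(0, 2, 1 / 64), phasic = 0, phasic_n = 0, tonic_n = 1
  )
  hr <- data.table(t = c(0, 1, 2), hr_n = c(60, 62, 64))
  m <- compute_window_measurements(
    events, pupil, phasic, hr,
    window = c(0, 2.01),
    ipi_thresholds = list(fix = 0.5, amp = 0.1)
  )
  expect_equal(m$cognitive_load, 0)
  expect_equal(m$mean_hr, 62)
  expect_equal(m$saccade_velocity, 4)
  expect_equal(m$eda_peaks, 0L)
  expect_equal(m$phasic_eda, 0)
  expect_equal(m$tonic_eda, 1)
  # one (fixation, saccade) pair: 1 s fixation >= 0.5 and 0.2 amp >= 0.1
  # is neither global nor local -> IPI = 1/1
  expect_equal(m$ipi, 1)
})
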