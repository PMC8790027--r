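#' @importFrom data.table data.table as.data.table rbindlist setorder setnames copy :=
#' @importFrom stats aov anova aggregate ar arima ave lm median oneway.test
#'   optim p.adjust pnorm predict quantile rbinom rgamma rlnorm rnorm rpois
#'   runif sd shapiro.test setNames var complete.cases coef residuals plogis
#'   qlogis
#' @importFrom utils head tail
NULL

# data.table NSE variables
utils::globalVariables(c(
  ".", ".N", ".SD", "participant", "domain", "game", "question", "phase",
  "t_start", "t_end", "measurement", "value", "window", "label", "usable",
  "t", "x", "y", "pupil_l", "pupil_r", "valid", "eda", "hr", "kind",
  "amplitude", "peak_velocity", "onset", "selection", "response", "correct",
  "displacement", "midpoint", "cycle_key", "aoi", "question_id", "n_values",
  "V1", "chosen", "norm_value", "p_adj", "significant", "effect_size",
  "cfe_class", "es_see_solve", "feedback", "rationale", "priority",
  "class_ord", "sig_rank", "es_rank", "affinity_rank", "in_top_any",
  "rank_see_solve", "rank_move", "rank_respond", "feature", "importance",
  "in_top", "precision", "recall", "f1", "untestable", "affinity",
  "welch_used", "ztransformed", "hr_n", "phasic_n", "tonic_n", "smoothed",
  "fix_dur", "F", "g", "mx", "my", "pv"
))

#' Derive a reproducible child seed from a base seed
#'
#' Splits one integer seed into per-unit streams (participants, folds,
#' repetitions) by a counter, keeping the result inside the 32-bit integer
#' range R requires for `set.seed()`.
#'
#' @param seed base integer seed
#' @param counter nonnegative integer identifying the child stream
#' @return an integer seed in `[0, 2^31 - 1)`
#' @export
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 1009 + 12345) %%
    2147483647)
}

# sample skewness (method-of-moments, as in e1071 type 1)
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

# excess kurtosis
sample_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((x - m)^4) / s2^2 - 3
}

#' Fit an order-2 autoregressive model
#'
#' Yule-Walker fit of an AR(2); returns the two coefficients or `NA` when the
#' series is too short or degenerate. Used for the AR1/AR2 features.
#'
#' @param x numeric series
#' @param min_n minimum series length for a fit
#' @return named numeric vector `c(ar1, ar2)`
#' @export
fit_ar2 <- function(x, min_n = 6L) {
  x <- x[is.finite(x)]
  if (length(x) < min_n || sd(x) == 0) {
    return(c(ar1 = NA_real_, ar2 = NA_real_))
  }
  fit <- try(stats::ar(x, aic = FALSE, order.max = 2L, method = "yule-walker"),
    silent = TRUE
  )
  if (inherits(fit, "try-error")) {
    return(c(ar1 = NA_real_, ar2 = NA_real_))
  }
  co <- fit$ar
  c(ar1 = unname(co[1]), ar2 = if (length(co) >= 2) unname(co[2]) else 0)
}

#' Fit a Gaussian GARCH(1,1) model by maximum likelihood
#'
#' Estimates the ARCH coefficient (alpha) and the GARCH coefficient (beta) of
#' a zero-mean GARCH(1,1) process by numerically maximizing the Gaussian
#' likelihood over (omega, alpha, beta) with a logistic parameterisation that
#' keeps alpha + beta < 1. Used for the GARCH features of each measurement
#' series; returns `NA` for series shorter than `min_n` or with zero variance.
#'
#' @param x numeric series (demeaned internally)
#' @param min_n minimum series length for a fit
#' @return named numeric vector `c(garch_alpha, garch_beta)`
#' @export
fit_garch11 <- function(x, min_n = 10L) {
  x <- x[is.finite(x)]
  if (length(x) < min_n || sd(x) == 0) {
    return(c(garch_alpha = NA_real_, garch_beta = NA_real_))
  }
  e <- x - mean(x)
  v0 <- var(e)
  negll <- function(par) {
    # par: log(omega), logit-ish alpha, beta fractions of remaining mass
    omega <- exp(par[1])
    ab <- 0.998 / (1 + exp(-par[2]))           # alpha + beta in (0, .998)
    afrac <- 1 / (1 + exp(-par[3]))
    alpha <- ab * afrac
    beta <- ab * (1 - afrac)
    h <- numeric(length(e))
    h[1] <- v0
    for (i in 2:length(e)) {
      h[i] <- omega + alpha * e[i - 1]^2 + beta * h[i - 1]
    }
    if (any(!is.finite(h)) || any(h <= 0)) return(1e10)
    0.5 * sum(log(h) + e^2 / h)
  }
  init <- c(log(v0 * 0.1), 0, 0)
  fit <- try(optim(init, negll, method = "Nelder-Mead",
    control = list(maxit = 500)), silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value)) {
    return(c(garch_alpha = NA_real_, garch_beta = NA_real_))
  }
  ab <- 0.998 / (1 + exp(-fit$par[2]))
  afrac <- 1 / (1 + exp(-fit$par[3]))
  c(garch_alpha = ab * afrac, garch_beta = ab * (1 - afrac))
}

# half-open rectangle membership: rect = c(x0, y0, x1, y1), origin top-left
point_in_rect <- function(x, y, rect) {
  x >= rect[1] & x < rect[3] & y >= rect[2] & y < rect[4]
}

# which AOI a point falls in: "question", "right", "wrong_<i>" or NA
classify_aoi <- function(x, y, layout) {
  out <- rep(NA_character_, length(x))
  out[point_in_rect(x, y, layout$question)] <- "question"
  for (i in seq_along(layout$options)) {
    opt <- layout$options[[i]]
    hit <- point_in_rect(x, y, opt$rect)
    out[hit] <- if (isTRUE(opt$correct)) "right" else paste0("wrong_", i)
  }
  out
}

# collapse wrong_<i> to the category level used for transition shares
aoi_category <- function(aoi) {
  ifelse(startsWith(aoi, "wrong"), "wrong", aoi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
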