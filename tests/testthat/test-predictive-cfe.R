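# Oversampling, participant-wise folds, the weighted ensemble, evaluation
# metrics, importance ranks and the predictive CFE classifier.

test_that("minority oversampling restores a 5:1 set to balance", {
  set.seed(1)
  x <- rbind(
    matrix(rnorm(50 * 4), ncol = 4), # majority
    matrix(rnorm(10 * 4, mean = 2), ncol = 4) # minority
  )
  y <- c(rep("right", 50), rep("wrong", 10))
  bal <- smote_balance(x, y, seed = 2)
  expect_equal(sum(bal$y == "wrong"), 50) # 10 original + 4 x 10 synthetic
  expect_equal(sum(bal$y == "right"), 50)
  # already balanced input returns unchanged
  xb <- x[1:20, ]
  yb <- rep(c("right", "wrong"), each = 10)
  bal2 <- smote_balance(xb, yb)
  expect_identical(bal2$x, xb)
  # too-small minority errors with pooling advice
  expect_error(
    smote_balance(x[1:53, ], c(rep("right", 50), rep("wrong", 3))),
    "pool"
  )
})

test_that("synthetic points stay inside the expanded neighbor box", {
  for (s in 1:20) {
    set.seed(s)
    n_min <- sample(6:15, 1)
    p <- sample(2:6, 1)
    x <- rbind(
      matrix(rnorm(40 * p), ncol = p),
      matrix(rnorm(n_min * p, mean = 1), ncol = p)
    )
    y <- c(rep("right", 40), rep("wrong", n_min))
    bal <- smote_balance(x, y, seed = s)
    synth <- bal$x[(nrow(x) + 1):nrow(bal$x), , drop = FALSE]
    xm <- x[y == "wrong", , drop = FALSE]
    d2 <- as.matrix(dist(xm))^2
    diag(d2) <- Inf
    for (i in seq_len(n_min)) {
      nb <- xm[order(d2[i, ])[1:4], , drop = FALSE]
      lo <- apply(nb, 2, min) - 0.5 * apply(nb, 2, sd) - 1e-9
      hi <- apply(nb, 2, max) + 0.5 * apply(nb, 2, sd) + 1e-9
      rows <- synth[(i - 1) * 4 + 1:4, , drop = FALSE]
      expect_true(all(t(rows) >= lo & t(rows) <= hi))
    }
  }
})

test_that("folds hold out 10% of participants and never leak", {
  ids40 <- sprintf("p%02d", 1:40)
  sp <- lopo_folds(rep(ids40, each = 3), seed = 5)
  expect_length(sp$holdout, 4L)
  expect_length(sp$folds, 36L)
  for (f in sp$folds) {
    expect_length(intersect(f$train, f$validation), 0L)
    expect_length(intersect(f$train, sp$holdout), 0L)
    expect_length(intersect(f$validation, sp$holdout), 0L)
  }
  # three participants: one held out, two folds
  sp3 <- lopo_folds(c("a", "b", "c"), seed = 1)
  expect_length(sp3$holdout, 1L)
  expect_length(sp3$folds, 2L)
  expect_error(lopo_folds(c("a", "b")), ">= 3")
})

test_that("ensemble weights normalize and separable data is learned", {
  blob <- make_blob_features(n_per_class = 40, sep = 3, seed = 3)
  tr <- c(1:30, 41:70)
  va <- c(31:35, 71:75)
  te <- c(36:40, 76:80)
  model <- fit_ensemble(
    blob$x[tr, ], blob$y[tr], blob$x[va, ], blob$y[va],
    seed = 9
  )
  expect_equal(sum(model$weights), 1)
  expect_true(all(model$weights >= 0))
  expect_length(model$members, 7L)
  ev <- predict_and_evaluate(model, blob$x[te, ], blob$y[te])
  acc <- (ev$tp + ev$tn) / length(te)
  expect_gt(acc, 0.9)
  # identical member scores make the ensemble equal any member
  sc_members <- vapply(
    model$members, function(m) carryforward:::member_score(m, blob$x[te, ]),
    numeric(length(te))
  )
  sc_ens <- ensemble_score(model, blob$x[te, ])
  expect_equal(as.numeric(sc_members %*% model$weights), sc_ens)
})

test_that("evaluation metrics implement the confusion formulas", {
  # 5 true positives, 1 false positive, no false negatives
  truth <- c(rep("right", 5), "wrong")
  pred <- rep("right", 6)
  ev <- evaluate_predictions(truth, pred)
  expect_equal(ev$precision, 5 / 6, tolerance = 1e-12)
  expect_equal(ev$recall, 1)
  # all correct
  ev2 <- evaluate_predictions(truth, truth)
  expect_equal(ev2$precision, 1)
  expect_equal(ev2$recall, 1)
  expect_equal(ev2$f1, 1)
  # random pairs vs a counting oracle
  set.seed(21)
  for (rep in 1:20) {
    tr <- sample(c("right", "wrong"), 50, replace = TRUE)
    pr <- sample(c("right", "wrong"), 50, replace = TRUE)
    ev3 <- evaluate_predictions(tr, pr)
    tp <- sum(tr == "right" & pr == "right")
    fp <- sum(tr == "wrong" & pr == "right")
    fn <- sum(tr == "right" & pr == "wrong")
    expect_equal(ev3$tp, tp)
    if (tp + fp > 0) expect_equal(ev3$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(ev3$recall, tp / (tp + fn))
    if (2 * tp + fp + fn > 0) {
      expect_equal(ev3$f1, 2 * tp / (2 * tp + fp + fn))
    }
  }
})

test_that("baseline metrics match their analytic values", {
  labels <- c(rep("right", 250), rep("wrong", 50))
  mb <- majority_baseline_metrics(labels)
  expect_equal(mb$precision, 5 / 6, tolerance = 1e-12)
  expect_equal(mb$recall, 1)
  rb <- random_baseline_metrics(rep(c("right", "wrong"), 50))
  expect_equal(rb$precision, 0.5)
  expect_equal(rb$recall, 0.5)
  expect_equal(rb$f1, 0.5)
})

test_that("importance ranks are dense and the top set sized by ceiling", {
  imp <- setNames(c(10, 10, 8, 5, 5, 1), paste0("f", 1:6))
  rt <- rank_feature_importance(imp, top_fraction = 0.34)
  expect_equal(rt$rank[rt$feature == "f1"], 1)
  expect_equal(rt$rank[rt$feature == "f2"], 1)
  expect_equal(rt$rank[rt$feature == "f3"], 2)
  expect_equal(rt$rank[rt$feature == "f6"], 4)
  expect_equal(sum(rt$in_top), sum(rt$rank <= ceiling(0.34 * 6)))
  # 140 features at the 10% fraction keep 14 ranks
  imp140 <- setNames(seq(140, 1), paste0("g", 1:140))
  rt140 <- rank_feature_importance(imp140, 0.10)
  expect_equal(sum(rt140$in_top), 14L)
})

test_that("pure-noise features rank below informative ones", {
  hits <- 0
  n_seeds <- 8
  for (s in 1:n_seeds) {
    blob <- make_blob_features(n_per_class = 35, n_noise = 6, sep = 2.5,
      seed = 100 + s)
    tr <- c(1:25, 36:60)
    va <- c(26:35, 61:70)
    model <- fit_ensemble(
      blob$x[tr, ], blob$y[tr], blob$x[va, ], blob$y[va],
      seed = s
    )
    imp <- permutation_importance(model, blob$x[va, ], blob$y[va], seed = s)
    rt <- rank_feature_importance(imp, 0.25)
    info_rank <- min(rt$rank[rt$feature %in% c("info1", "info2")])
    noise_ranks <- rt$rank[startsWith(rt$feature, "noise")]
    if (info_rank <= min(noise_ranks)) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("the predictive CFE classifier covers orderings, ties, top sets", {
  # published rank rows: HR mean 5/6/8 Perfect; SV SD 2/5/4 Pseudo;
  # HR SD in the top set only for See-Solve -> none
  expect_identical(
    classify_cfe_predictive(c(5, 6, 8), c(TRUE, TRUE, TRUE))$cfe_class,
    "perfect"
  )
  expect_identical(
    classify_cfe_predictive(c(2, 5, 4), c(TRUE, TRUE, TRUE))$cfe_class,
    "pseudo"
  )
  expect_identical(
    classify_cfe_predictive(c(7, NA, NA), c(TRUE, FALSE, FALSE))$cfe_class,
    "none"
  )
  # exhaustive truth table over rank orderings and top-set membership
  ranks3 <- expand.grid(r1 = 1:3, r2 = 1:3, r3 = 1:3)
  tops <- expand.grid(
    t1 = c(TRUE, FALSE), t2 = c(TRUE, FALSE), t3 = c(TRUE, FALSE)
  )
  for (i in seq_len(nrow(ranks3))) {
    for (j in seq_len(nrow(tops))) {
      r <- as.numeric(ranks3[i, ])
      tp <- as.logical(tops[j, ])
      got <- classify_cfe_predictive(r, tp)$cfe_class
      want <- if (!all(tp)) {
        "none"
      } else if (r[1] < r[2] && r[1] < r[3] && r[2] < r[3]) {
        "perfect"
      } else if (r[1] < r[2] && r[1] < r[3]) {
        "pseudo"
      } else {
        "none"
      }
      expect_identical(got, want)
    }
  }
})

test_that("duplicating a feature barely moves unrelated ranks", {
  blob <- make_blob_features(n_per_class = 35, n_noise = 4, sep = 2.5,
    seed = 55)
  tr <- c(1:25, 36:60)
  va <- c(26:35, 61:70)
  model <- fit_ensemble(blob$x[tr, ], blob$y[tr], blob$x[va, ], blob$y[va],
    seed = 7)
  imp <- permutation_importance(model, blob$x[va, ], blob$y[va], seed = 7)
  rt <- rank_feature_importance(imp, 0.5)
  x_dup <- cbind(blob$x, info1_copy = blob$x[, "info1"])
  model2 <- fit_ensemble(x_dup[tr, ], blob$y[tr], x_dup[va, ], blob$y[va],
    seed = 7)
  imp2 <- permutation_importance(model2, x_dup[va, ], blob$y[va], seed = 7)
  rt2 <- rank_feature_importance(imp2, 0.5)
  r_before <- rt$rank[rt$feature == "info2"]
  r_after <- rt2$rank[rt2$feature == "info2"]
  expect_lte(abs(r_after - r_before), 2)
})
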