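# Predictive carry-forward analysis: correctness prediction from the
# per-phase feature vectors with a validation-weighted seven-member ensemble
# (SVMs and Gaussian-process classifiers with linear/radial/polynomial
# kernels, plus a model tree), leave-one-participant-out cross-validation
# with a held-out participant set, minority oversampling inside training
# folds only, permutation feature importance, and the rank-based CFE
# classification.

#' Oversample the minority class (nearest-neighbor mean variant)
#'
#' For each minority point the five nearest minority neighbors (Euclidean)
#' are found; four synthetic points are generated from the mean of the
#' point's four closest neighbors, jittered by +25%, -25%, +50% and -50% of
#' those neighbors' per-feature SD respectively. Only the minority class is
#' augmented; an already balanced set is returned unchanged.
#'
#' @param x numeric feature matrix (rows = observations)
#' @param y label vector with two levels
#' @param seed integer seed for the jitter signs' pairing with points
#' @return list `x`, `y` with synthetic minority rows appended
#' @export
smote_balance <- function(x, y, seed = 1L) {
  x <- as.matrix(x)
  tab <- table(y)
  if (length(tab) < 2L) stopf("smote_balance: single-class input")
  if (tab[1] == tab[2]) {
    return(list(x = x, y = y))
  }
  minority <- names(tab)[which.min(tab)]
  idx <- which(y == minority)
  if (length(idx) < 5L) {
    stopf(
      "minority class has %d points (< 5); pool data across games or domains",
      length(idx)
    )
  }
  set.seed(seed)
  xm <- x[idx, , drop = FALSE]
  d2 <- as.matrix(stats::dist(xm))^2
  diag(d2) <- Inf
  jitter_frac <- c(0.25, -0.25, 0.5, -0.5)
  synth <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    nn5 <- order(d2[i, ])[1:5]
    nn4 <- nn5[1:4] # the point's four closest neighbors
    nb <- xm[nn4, , drop = FALSE]
    center <- colMeans(nb)
    nb_sd <- apply(nb, 2, sd)
    synth[[i]] <- t(vapply(
      jitter_frac, function(f) center + f * nb_sd, numeric(ncol(x))
    ))
  }
  synth <- do.call(rbind, synth)
  list(
    x = rbind(x, synth),
    y = c(y, rep(minority, nrow(synth)))
  )
}

#' Leave-one-participant-out folds behind a participant holdout
#'
#' 10% of the participants (rounded up, seeded) form the outer test
#' holdout; the remaining participants are cycled leave-one-out as
#' train/validation splits. No participant ever appears on both sides of a
#' split.
#'
#' @param participant_ids vector of (possibly repeated) participant ids
#' @param holdout_fraction outer holdout share (default 0.10)
#' @param seed integer seed for the holdout draw
#' @return list `holdout` (participant ids) and `folds` (list of lists with
#'   `train` and `validation` participant id vectors)
#' @export
lopo_folds <- function(participant_ids, holdout_fraction = 0.10, seed = 1L) {
  ids <- sort(unique(participant_ids))
  if (length(ids) < 3L) stopf("need >= 3 participants, got %d", length(ids))
  set.seed(seed)
  n_hold <- ceiling(holdout_fraction * length(ids))
  holdout <- sort(sample(ids, n_hold))
  rest <- setdiff(ids, holdout)
  folds <- lapply(rest, function(v) {
    list(train = setdiff(rest, v), validation = v)
  })
  list(holdout = holdout, folds = folds)
}

# ---------------------------------------------------------------------------
# ensemble members: each returns an object with a score() giving
# P(class = "right") in [0, 1]

MEMBER_KINDS <- c(
  "svm_linear", "svm_radial", "svm_polynomial",
  "gp_linear", "gp_radial", "gp_polynomial",
  "model_tree"
)

# inverse median squared pairwise distance over (at most) 80 rows
rbf_sigma <- function(x) {
  n <- nrow(x)
  idx <- if (n > 80) round(seq(1, n, length.out = 80)) else seq_len(n)
  d2 <- stats::dist(x[idx, , drop = FALSE])^2
  m <- median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) m <- 1
  1 / m
}

fit_member <- function(kind, x, y, seed = 1L) {
  y <- factor(y, levels = c("wrong", "right"))
  set.seed(seed) # e1071 probability calibration uses the RNG
  obj <- switch(kind,
    svm_linear = ,
    svm_radial = ,
    svm_polynomial = {
      kern <- sub("svm_", "", kind)
      kern <- if (kern == "polynomial") "polynomial" else kern
      e1071::svm(
        x = x, y = y, kernel = kern, degree = 2, probability = TRUE,
        scale = apply(x, 2, sd) > 0
      )
    },
    gp_linear = ,
    gp_radial = ,
    gp_polynomial = {
      kern <- switch(sub("gp_", "", kind),
        linear = "vanilladot", radial = "rbfdot", polynomial = "polydot"
      )
      kpar <- switch(kern,
        vanilladot = list(),
        # deterministic median-distance bandwidth heuristic
        rbfdot = list(sigma = rbf_sigma(x)),
        polydot = list(degree = 2, scale = 0.1, offset = 1)
      )
      # cap the GP training set (cubic cost in n): stratified deterministic
      # thinning keeps both classes represented
      cap <- 150L
      if (nrow(x) > cap) {
        idx <- unlist(lapply(split(seq_len(nrow(x)), y), function(ii) {
          ii[round(seq(1, length(ii), length.out = ceiling(
            cap * length(ii) / nrow(x)
          )))]
        }))
        idx <- sort(unique(idx))
        x <- x[idx, , drop = FALSE]
        y <- y[idx]
      }
      suppressWarnings(kernlab::gausspr(
        x = x, y = y, kernel = kern, kpar = kpar
      ))
    },
    model_tree = fit_model_tree(x, y),
    stopf("unknown member kind '%s'", kind)
  )
  structure(list(kind = kind, fit = obj, levels = levels(y)),
    class = "ensemble_member"
  )
}

member_score <- function(member, x) {
  x <- as.matrix(x)
  if (member$kind == "model_tree") {
    return(predict_model_tree(member$fit, x))
  }
  if (startsWith(member$kind, "svm")) {
    pr <- attr(
      predict(member$fit, x, probability = TRUE), "probabilities"
    )
    return(unname(pr[, "right"]))
  }
  pr <- try(kernlab::predict(member$fit, x, type = "probabilities"),
    silent = TRUE
  )
  if (!inherits(pr, "try-error") && is.matrix(pr) &&
    "right" %in% colnames(pr)) {
    return(unname(pr[, "right"]))
  }
  # fall back to hard labels when the probability model is unavailable
  as.numeric(kernlab::predict(member$fit, x) == "right")
}

# M5-style model tree: a pruned regression tree on the 0/1 response with a
# linear model in each leaf (leaf mean when the local fit is degenerate)
fit_model_tree <- function(x, y) {
  y01 <- as.numeric(y == "right")
  df <- data.frame(x, check.names = TRUE)
  tree <- rpart::rpart(
    y01 ~ ., data = cbind(y01 = y01, df),
    method = "anova",
    control = rpart::rpart.control(
      minbucket = 10, cp = 0.01, xval = 0, maxdepth = 5
    )
  )
  leaves <- tree$where
  leaf_models <- lapply(unique(leaves), function(l) {
    rows <- which(leaves == l)
    if (length(rows) < ncol(x) + 5 || length(rows) < 8) {
      return(list(type = "mean", value = mean(y01[rows])))
    }
    # keep the few most label-correlated columns to keep the fit stable
    sds <- apply(df[rows, , drop = FALSE], 2, sd)
    usable <- names(sds)[sds > 0]
    if (!length(usable)) {
      return(list(type = "mean", value = mean(y01[rows])))
    }
    if (sd(y01[rows]) == 0) {
      return(list(type = "mean", value = mean(y01[rows])))
    }
    cors <- abs(suppressWarnings(vapply(
      usable, function(cn) stats::cor(df[rows, cn], y01[rows]), 0
    )))
    cors[!is.finite(cors)] <- 0
    keep <- usable[order(-cors)][seq_len(min(3, length(usable)))]
    fml <- stats::as.formula(paste("y01 ~", paste(keep, collapse = "+")))
    fit <- lm(fml, data = cbind(y01 = y01[rows], df[rows, , drop = FALSE]))
    list(type = "lm", fit = fit)
  })
  names(leaf_models) <- as.character(unique(leaves))
  list(tree = tree, leaf_models = leaf_models, columns = colnames(df))
}

predict_model_tree <- function(model, x) {
  df <- data.frame(x, check.names = TRUE)
  names(df) <- model$columns[seq_len(ncol(df))]
  # route rows to leaves via the fitted tree
  pred_node <- function(tree, newdata) {
    # rpart predicts leaf means; map rows to leaves through the frame
    fit <- predict(tree, newdata = newdata)
    leaf_mean <- tree$frame$yval[tree$where]
    # match by predicted value to the training leaf set
    frame_leaves <- which(tree$frame$var == "<leaf>")
    means <- tree$frame$yval[frame_leaves]
    where <- frame_leaves[max.col(-abs(outer(fit, means, `-`)))]
    where
  }
  where <- pred_node(model$tree, df)
  out <- numeric(nrow(df))
  for (lf in unique(where)) {
    rows <- which(where == lf)
    mdl <- model$leaf_models[[as.character(lf)]]
    if (is.null(mdl)) {
      out[rows] <- predict(model$tree, newdata = df[rows, , drop = FALSE])
    } else if (mdl$type == "mean") {
      out[rows] <- mdl$value
    } else {
      # leaf fits may be rank-deficient on small validation leaves
      out[rows] <- suppressWarnings(
        predict(mdl$fit, newdata = df[rows, , drop = FALSE])
      )
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Fit the validation-weighted seven-member ensemble
#'
#' Members are fit on the (already oversampled) training set; each member's
#' weight is its validation accuracy divided by the members' summed
#' accuracy (uniform when all accuracies are zero).
#'
#' @param x_train,y_train balanced training data
#' @param x_val,y_val validation data (never resampled)
#' @param seed integer seed
#' @return `ensemble_model` list: `members`, `weights`, `threshold`
#' @export
fit_ensemble <- function(x_train, y_train, x_val, y_val, seed = 1L) {
  if (length(unique(y_train)) < 2L) {
    stopf("fit_ensemble: single-class training set")
  }
  x_train <- as.matrix(x_train)
  x_val <- as.matrix(x_val)
  members <- lapply(seq_along(MEMBER_KINDS), function(i) {
    fit_member(MEMBER_KINDS[i], x_train, y_train, derive_seed(seed, i))
  })
  names(members) <- MEMBER_KINDS
  acc <- vapply(members, function(m) {
    sc <- member_score(m, x_val)
    mean((sc >= 0.5) == (y_val == "right"))
  }, 0)
  weights <- if (sum(acc) == 0) {
    rep(1 / length(acc), length(acc))
  } else {
    acc / sum(acc)
  }
  structure(
    list(
      members = members, weights = setNames(weights, MEMBER_KINDS),
      threshold = 0.5, accuracies = acc
    ),
    class = "ensemble_model"
  )
}

#' Weighted ensemble score
#'
#' @param model an `ensemble_model`
#' @param x feature matrix
#' @return numeric scores in `[0, 1]` (probability-like for class "right")
#' @export
ensemble_score <- function(model, x) {
  scores <- vapply(
    model$members, function(m) member_score(m, x), numeric(nrow(as.matrix(x)))
  )
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  as.numeric(scores %*% model$weights)
}

#' Confusion metrics with "right" as the positive class
#'
#' @param truth,pred label vectors ("right"/"wrong")
#' @return `evaluation_result` list: `tp`, `fp`, `tn`, `fn`, `precision`,
#'   `recall`, `f1`
#' @export
evaluate_predictions <- function(truth, pred) {
  tp <- sum(truth == "right" & pred == "right")
  fp <- sum(truth == "wrong" & pred == "right")
  tn <- sum(truth == "wrong" & pred == "wrong")
  fn <- sum(truth == "right" & pred == "wrong")
  structure(
    list(
      tp = tp, fp = fp, tn = tn, fn = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    ),
    class = "evaluation_result"
  )
}

#' Score a test set and evaluate
#'
#' @param model an `ensemble_model`
#' @param x,y test data
#' @return an `evaluation_result`
#' @export
predict_and_evaluate <- function(model, x, y) {
  stopifnot(nrow(as.matrix(x)) > 0)
  sc <- ensemble_score(model, x)
  pred <- ifelse(sc >= model$threshold, "right", "wrong")
  evaluate_predictions(y, pred)
}

#' Majority-class baseline metrics
#'
#' The classifier that always predicts the majority label ("right" under the
#' study's ~5:1 imbalance).
#'
#' @param labels label vector
#' @return an `evaluation_result`
#' @export
majority_baseline_metrics <- function(labels) {
  majority <- names(which.max(table(labels)))
  evaluate_predictions(labels, rep(majority, length(labels)))
}

#' Expected metrics of a uniform random classifier
#'
#' Analytic expectation: recall is 1/2 regardless of the label mix; the
#' expected precision equals the positive-class share p; F1 is the
#' plug-in 2 * p * (1/2) / (p + 1/2).
#'
#' @param labels label vector (positive class "right")
#' @return list `precision`, `recall`, `f1`
#' @export
random_baseline_metrics <- function(labels) {
  p <- mean(labels == "right")
  list(
    precision = p, recall = 0.5,
    f1 = 2 * p * 0.5 / (p + 0.5)
  )
}

# median imputation learned on the training rows only; all-missing columns
# impute to 0
impute_medians <- function(x_train) {
  med <- apply(x_train, 2, function(col) {
    m <- median(col, na.rm = TRUE)
    if (is.finite(m)) m else 0
  })
  med
}

apply_impute <- function(x, med) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[j]
  }
  x
}

#' Run the predictive pipeline on one (domain, phase) feature set
#'
#' Splits participants into a seeded outer holdout plus
#' leave-one-participant-out folds; inside each fold imputes medians from
#' the training rows, oversamples the training minority, fits the
#' seven-member ensemble and computes validation accuracy weights and
#' permutation importances. A final ensemble fit on all non-holdout data is
#' evaluated on the untouched holdout.
#'
#' @param features wide feature table of one (domain, phase)
#' @param seed integer seed
#' @param holdout_fraction outer holdout share
#' @return list: `metrics` (`evaluation_result` on the holdout),
#'   `importance` (per-feature score averaged over folds, 0-100 scale),
#'   `fold_weights`, `n_folds`
#' @export
run_predictive_phase <- function(features, seed = 1L,
                                 holdout_fraction = 0.10) {
  meta_cols <- c("participant", "domain", "question", "phase", "label")
  feat_cols <- setdiff(names(features), meta_cols)
  x_all <- as.matrix(features[, feat_cols, with = FALSE])
  y_all <- features$label
  pid <- features$participant

  sp <- lopo_folds(pid, holdout_fraction, derive_seed(seed, 1))
  in_hold <- pid %in% sp$holdout

  imp_folds <- list()
  weight_folds <- list()
  for (k in seq_along(sp$folds)) {
    f <- sp$folds[[k]]
    tr <- pid %in% f$train
    va <- pid %in% f$validation
    if (length(unique(y_all[tr])) < 2L || sum(va) == 0) next
    med <- impute_medians(x_all[tr, , drop = FALSE])
    xtr <- apply_impute(x_all[tr, , drop = FALSE], med)
    xva <- apply_impute(x_all[va, , drop = FALSE], med)
    bal <- smote_balance(xtr, y_all[tr], derive_seed(seed, 100 + k))
    model <- fit_ensemble(
      bal$x, bal$y, xva, y_all[va],
      derive_seed(seed, 200 + k)
    )
    imp_folds[[length(imp_folds) + 1L]] <- permutation_importance(
      model, xva, y_all[va],
      seed = derive_seed(seed, 300 + k)
    )
    weight_folds[[length(weight_folds) + 1L]] <- model$weights
  }
  if (!length(imp_folds)) stopf("no usable folds")
  importance <- Reduce(`+`, imp_folds) / length(imp_folds)
  # scale to 0-100
  if (max(importance) > 0) {
    importance <- 100 * importance / max(importance)
  }

  # final model on all non-holdout participants, evaluated on the holdout
  tr <- !in_hold
  med <- impute_medians(x_all[tr, , drop = FALSE])
  xtr <- apply_impute(x_all[tr, , drop = FALSE], med)
  xho <- apply_impute(x_all[in_hold, , drop = FALSE], med)
  bal <- smote_balance(xtr, y_all[tr], derive_seed(seed, 400))
  model <- fit_ensemble(
    bal$x, bal$y, xho, y_all[in_hold],
    derive_seed(seed, 401)
  )
  metrics <- predict_and_evaluate(model, xho, y_all[in_hold])

  list(
    metrics = metrics,
    importance = importance,
    fold_weights = weight_folds,
    n_folds = length(imp_folds)
  )
}

#' Weight-combined permutation importance of one fitted ensemble
#'
#' For every member the accuracy drop on the validation set after permuting
#' each feature column (one seeded permutation) is computed; member drops
#' are combined by the ensemble weights. Negative drops clip to zero.
#'
#' @param model an `ensemble_model`
#' @param x_val,y_val validation data
#' @param seed integer seed for the permutation
#' @return named numeric vector of importances
#' @export
permutation_importance <- function(model, x_val, y_val, seed = 1L) {
  x_val <- as.matrix(x_val)
  n <- nrow(x_val)
  p <- ncol(x_val)
  set.seed(seed)
  perm <- sample.int(n)
  out <- setNames(numeric(p), colnames(x_val))
  right <- y_val == "right"
  # stack the p single-column-permuted copies for one predict per member
  x_big <- x_val[rep(seq_len(n), p), , drop = FALSE]
  for (j in seq_len(p)) {
    rows <- (j - 1L) * n + seq_len(n)
    x_big[rows, j] <- x_val[perm, j]
  }
  for (m in seq_along(model$members)) {
    w <- model$weights[m]
    if (w == 0) next
    base_sc <- member_score(model$members[[m]], x_val)
    base_acc <- mean((base_sc >= 0.5) == right)
    sc <- member_score(model$members[[m]], x_big)
    acc <- colMeans(matrix((sc >= 0.5) == right, nrow = n))
    out <- out + w * pmax(base_acc - acc, 0)
  }
  out
}

#' Dense importance ranks and top-set membership
#'
#' @param importance named importance vector of one phase
#' @param top_fraction top share defining the important set
#' @return data.table `feature`, `importance`, `rank` (dense, 1 = most
#'   important), `in_top`
#' @export
rank_feature_importance <- function(importance, top_fraction = 0.10) {
  ord <- order(-importance)
  dense <- match(-importance, sort(unique(-importance)))
  k <- length(importance)
  top_k <- ceiling(top_fraction * k)
  data.table(
    feature = names(importance),
    importance = as.numeric(importance),
    rank = dense,
    in_top = dense <= top_k
  )[order(rank, feature)]
}

#' Classify the predictive carry-forward effect of one feature
#'
#' "Rank highest" means numerically smallest. Perfect: in the top set in all
#' three phases and rank(See-Solve) < rank(Move) < rank(Respond). Pseudo: in
#' the top set everywhere, the See-Solve rank strictly smallest, but the
#' Move rank not below the Respond rank. Ties fail the strict comparisons.
#'
#' @param ranks numeric `c(see_solve, move, respond)` (NA allowed)
#' @param in_top logical `c(see_solve, move, respond)`
#' @return `cfe_result` list with `cfe_class` and condition booleans
#' @export
classify_cfe_predictive <- function(ranks, in_top) {
  stopifnot(length(ranks) == 3L, length(in_top) == 3L)
  res <- list(
    cfe_class = "none",
    in_top_all = all(in_top %in% TRUE),
    ss_highest = FALSE, move_above_respond = FALSE
  )
  class(res) <- "cfe_result"
  if (!res$in_top_all || anyNA(ranks)) {
    return(res)
  }
  res$ss_highest <- ranks[1] < ranks[2] && ranks[1] < ranks[3]
  res$move_above_respond <- ranks[2] < ranks[3]
  if (res$ss_highest && res$move_above_respond) {
    res$cfe_class <- "perfect"
  } else if (res$ss_highest) {
    res$cfe_class <- "pseudo"
  }
  res
}

#' Predictive CFE table across the three phases of a domain
#'
#' @param rank_tables named list (`see_solve`, `move`, `respond`) of
#'   [rank_feature_importance()] outputs
#' @return data.table: one row per feature with per-phase ranks (NA when not
#'   in that phase's top set) and the CFE class
#' @export
cfe_predictive_table <- function(rank_tables) {
  phases <- c("see_solve", "move", "respond")
  stopifnot(all(phases %in% names(rank_tables)))
  feats <- rank_tables$see_solve$feature
  rows <- lapply(feats, function(f) {
    ranks <- vapply(phases, function(p) {
      rt <- rank_tables[[p]]
      rt$rank[rt$feature == f]
    }, 0)
    tops <- vapply(phases, function(p) {
      rt <- rank_tables[[p]]
      isTRUE(rt$in_top[rt$feature == f])
    }, TRUE)
    r <- classify_cfe_predictive(ranks, tops)
    data.table(
      feature = f,
      rank_see_solve = ifelse(tops[1], ranks[1], NA_real_),
      rank_move = ifelse(tops[2], ranks[2], NA_real_),
      rank_respond = ifelse(tops[3], ranks[3], NA_real_),
      in_top_any = any(tops),
      cfe_class = r$cfe_class
    )
  })
  rbindlist(rows)
}
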