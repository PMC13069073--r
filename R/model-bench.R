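# Rank-statistic AUC: probability that a positive outranks a negative,
# ties counted 1/2. Shared by the benchmark metrics and the panel filter.
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro one-vs-rest AUC-ROC
#'
#' Mean over classes of the binary AUC obtained by scoring each class's
#' predicted probability against "that class vs the rest".
#'
#' @param P samples x classes probability matrix (named columns).
#' @param y true class labels.
#' @return macro-averaged AUC in `[0, 1]`.
#' @export
macro_ovr_auc <- function(P, y) {
  y <- as.character(y)
  aucs <- vapply(colnames(P), function(cls) auc_rank(P[, cls], y == cls),
                 numeric(1))
  mean(aucs, na.rm = TRUE)
}

# Out-of-fold predictions for every model over a repeated-CV scheme.
# Standardization is fitted on each training fold only (leakage-safe).
# Returns list(classes, folds, repeats = list of list(prob = model->matrix,
# pred = model->character)).
cv_predictions <- function(X, y, models, scheme, seed = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  seed <- if (is.null(seed)) scheme$seed else seed
  folds <- make_folds(y, scheme, seed)
  classes <- class_levels(y)
  n <- nrow(X)
  reps <- vector("list", scheme$n_repeats)
  for (r in seq_len(scheme$n_repeats)) {
    prob <- lapply(models, function(m) {
      P <- matrix(NA_real_, n, length(classes),
                  dimnames = list(rownames(X), classes))
      P
    })
    for (f in seq_len(scheme$n_folds)) {
      test <- which(folds[[r]] == f)
      train <- setdiff(seq_len(n), test)
      if (length(unique(y[train])) < length(classes))
        stop("stratification error: class absent from a training fold")
      st <- fit_standardizer(X, train)
      Xtr <- apply_standardizer(st, X)[train, , drop = FALSE]
      Xte <- apply_standardizer(st, X)[test, , drop = FALSE]
      for (mi in seq_along(models)) {
        fs <- child_seed(seed, r * 1000L + f * 10L + mi)
        fit <- fit_model(models[[mi]], Xtr, y[train], seed = fs)
        prob[[mi]][test, ] <- predict_prob(fit, Xte)
      }
    }
    pred <- lapply(prob, function(P)
      colnames(P)[max.col(P, ties.method = "first")])
    reps[[r]] <- list(prob = prob, pred = pred)
  }
  list(classes = classes, folds = folds, repeats = reps,
       model_names = names(models))
}

rep_metrics <- function(P, pred, y, classes) {
  acc <- mean(pred == y)
  prec <- vapply(classes, function(cls) {
    tp <- sum(pred == cls & y == cls); fp <- sum(pred == cls & y != cls)
    if (tp + fp == 0) 0 else tp / (tp + fp)
  }, numeric(1))
  rec <- vapply(classes, function(cls) {
    tp <- sum(pred == cls & y == cls); fn <- sum(pred != cls & y == cls)
    if (tp + fn == 0) 0 else tp / (tp + fn)
  }, numeric(1))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  c(accuracy = acc,
    precision_macro = mean(prec),
    recall_micro = acc,   # micro-averaged recall equals accuracy here
    f1_macro = mean(f1),
    auc_macro_ovr = macro_ovr_auc(P, y))
}

#' Benchmark the classifier bank on a feature panel
#'
#' Restricts `X` to the panel features, runs every model through the
#' repeated stratified CV scheme (standardization fitted per training
#' fold), and aggregates out-of-fold metrics per repetition: accuracy,
#' macro-averaged precision, micro-averaged recall, macro F1 and macro
#' one-vs-rest AUC-ROC. Point estimate = mean over repetitions; the 95%
#' interval is the 2.5/97.5 percentile over repetition-level scores.
#'
#' @param X samples x features numeric matrix.
#' @param y class labels.
#' @param panel a `feature_panel` or character vector of feature names.
#' @param scheme a [cv_scheme()] (the evaluation default is 20-repeated
#'   stratified threefold).
#' @param models classifier bank from [build_classifiers()].
#' @param seed optional seed override.
#' @return a `metric_report` data.frame (`model`, `metric`, `value`,
#'   `lower`, `upper`) with the per-repetition scores and out-of-fold
#'   predictions attached as attributes `rep_scores` and `predictions`.
#' @export
evaluate_models <- function(X, y, panel = colnames(X),
                            scheme = cv_scheme(20, 3),
                            models = build_classifiers(), seed = NULL) {
  feats <- panel_features(panel)
  missing <- setdiff(feats, colnames(X))
  if (length(missing) > 0)
    stop("panel feature(s) absent from X: ", paste(missing, collapse = ", "))
  if (length(feats) == 0) stop("empty panel")
  Xp <- as.matrix(X)[, feats, drop = FALSE]
  y <- as.character(y)
  cp <- cv_predictions(Xp, y, models, scheme, seed)
  metric_names <- c("accuracy", "precision_macro", "recall_micro",
                    "f1_macro", "auc_macro_ovr")
  rows <- list()
  rep_scores <- list()
  for (mi in seq_along(models)) {
    scores <- t(vapply(cp$repeats, function(rp)
      rep_metrics(rp$prob[[mi]], rp$pred[[mi]], y, cp$classes),
      numeric(length(metric_names))))
    rep_scores[[names(models)[mi]]] <- scores
    for (met in metric_names) {
      v <- scores[, met]
      rows[[length(rows) + 1]] <- data.frame(
        model = names(models)[mi], metric = met,
        value = mean(v),
        lower = unname(quantile(v, 0.025, type = 7)),
        upper = unname(quantile(v, 0.975, type = 7)),
        stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  attr(rep, "rep_scores") <- rep_scores
  attr(rep, "predictions") <- cp
  class(rep) <- c("metric_report", class(rep))
  rep
}

#' Permutation significance test of a classifier
#'
#' Observed statistic: cross-validated macro one-vs-rest AUC on the true
#' labels. Null distribution: the same quantity recomputed after each of
#' `n_shuffles` random label permutations. The p-value uses the add-one
#' formula `(1 + #{null >= observed}) / (1 + n_shuffles)`, so its floor is
#' `1/(n_shuffles + 1)` — calling p < 0.001 needs at least 1000 shuffles.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param model a single `model_spec`.
#' @param scheme CV scheme used for both observed and null AUCs.
#' @param n_shuffles number of label permutations (default 1000).
#' @param seed RNG seed.
#' @return a `permutation_test_result` list: `observed`, `null_auc`
#'   (one per shuffle), `mean_null`, `p_value`, `n_shuffles`.
#' @export
permutation_test <- function(X, y, model, scheme = cv_scheme(1, 3),
                             n_shuffles = 1000L, seed = 1L) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  y <- as.character(y)
  if (length(unique(y)) < 2) stop("degenerate single-class labels")
  models <- list(model); names(models) <- model$name
  cv_auc <- function(yy, s) {
    cp <- cv_predictions(X, yy, models, scheme, seed = s)
    mean(vapply(cp$repeats, function(rp)
      macro_ovr_auc(rp$prob[[1]], yy), numeric(1)))
  }
  observed <- cv_auc(y, child_seed(seed, 0L))
  null_auc <- with_seed(seed, {
    perms <- replicate(n_shuffles, sample(y), simplify = FALSE)
    vapply(seq_len(n_shuffles), function(b)
      cv_auc(perms[[b]], child_seed(seed, b)), numeric(1))
  })
  structure(list(observed = observed, null_auc = null_auc,
                 mean_null = mean(null_auc),
                 p_value = (1 + sum(null_auc >= observed)) / (1 + n_shuffles),
                 n_shuffles = n_shuffles, model = model$name),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("<permutation test> %s: observed AUC %.3f, mean null AUC %.3f, p = %.4g (%d shuffles)\n",
              x$model, x$observed, x$mean_null, x$p_value, x$n_shuffles))
  invisible(x)
}

#' Consensus feature-importance ranking
#'
#' Per CV fold and model, per-feature importance is the native impurity
#' importance (RF, ETC, AB), the mean absolute one-vs-rest coefficient
#' (LSVM), or the univariate F statistic (NB fallback). Each model's score
#' vector is normalized to sum 1 and averaged over folds; the consensus
#' rank is the mean rank across models. Occlusion-based additive
#' attribution scores (a cheap SHAP-style approximation: mean absolute
#' change in the true-class probability when a feature is replaced by its
#' training mean) can be reported alongside but never alter the consensus
#' rank.
#'
#' @inheritParams evaluate_models
#' @param include_attribution also compute occlusion attribution scores.
#' @return data.frame with one row per feature: normalized mean importance
#'   per model, `consensus_rank`, and optionally `attribution`.
#' @export
consensus_importance <- function(X, y, panel = colnames(X),
                                 models = build_classifiers(),
                                 scheme = cv_scheme(3, 5), seed = NULL,
                                 include_attribution = FALSE) {
  feats <- panel_features(panel)
  Xp <- as.matrix(X)[, feats, drop = FALSE]
  y <- as.character(y)
  seed <- if (is.null(seed)) scheme$seed else seed
  folds <- make_folds(y, scheme, seed)
  acc <- matrix(0, length(feats), length(models),
                dimnames = list(feats, names(models)))
  attr_acc <- numeric(length(feats))
  n_folds_total <- 0L
  for (r in seq_len(scheme$n_repeats)) {
    for (f in seq_len(scheme$n_folds)) {
      train <- which(folds[[r]] != f)
      st <- fit_standardizer(Xp, train)
      Xtr <- apply_standardizer(st, Xp)[train, , drop = FALSE]
      ytr <- y[train]
      n_folds_total <- n_folds_total + 1L
      for (mi in seq_along(models)) {
        fs <- child_seed(seed, r * 1000L + f * 10L + mi)
        fit <- fit_model(models[[mi]], Xtr, ytr, seed = fs)
        imp <- model_importance(fit)
        if (is.null(imp)) imp <- f_statistic(Xtr, ytr)
        imp <- abs(imp)
        tot <- sum(imp)
        if (tot > 0) imp <- imp / tot else imp <- rep(1 / length(imp), length(imp))
        acc[, mi] <- acc[, mi] + imp[feats]
        if (include_attribution && mi == 1) {
          P0 <- predict_prob(fit, Xtr)
          p_true <- P0[cbind(seq_len(nrow(Xtr)), match(ytr, colnames(P0)))]
          for (jj in seq_along(feats)) {
            Xm <- Xtr
            Xm[, jj] <- mean(Xtr[, jj])
            Pm <- predict_prob(fit, Xm)
            attr_acc[jj] <- attr_acc[jj] +
              mean(abs(p_true - Pm[cbind(seq_len(nrow(Xm)),
                                         match(ytr, colnames(Pm)))]))
          }
        }
      }
    }
  }
  acc <- acc / n_folds_total
  ranks <- apply(-acc, 2, rank, ties.method = "average")
  out <- data.frame(feature = feats, acc,
                    consensus_rank = rowMeans(ranks),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (include_attribution) out$attribution <- attr_acc / n_folds_total
  out[order(out$consensus_rank, out$feature), , drop = FALSE]
}

panel_features <- function(panel) {
  if (inherits(panel, "feature_panel")) panel$feature else as.character(panel)
}
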