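test_that("the bank exposes exactly five probabilistic, seeded classifiers", {
  models <- build_classifiers()
  expect_identical(names(models), c("NB", "LSVM", "RF", "ETC", "AB"))
  expect_error(build_classifiers(names = "XGB"), "unknown")

  tc <- toy_classes(n_per = 15, sep = 3)
  for (m in models) {
    fit <- fit_model(m, tc$X, tc$y, seed = 11)
    P <- predict_prob(fit, tc$X)
    expect_equal(unname(rowSums(P)), rep(1, nrow(tc$X)), tolerance = 1e-9)
    expect_true(all(P >= 0))
    # determinism under a fixed seed
    fit2 <- fit_model(m, tc$X, tc$y, seed = 11)
    expect_identical(predict_prob(fit2, tc$X), P)
  }
})

test_that("evaluate_models matches a confusion-matrix oracle and chance levels", {
  tc <- toy_classes(n_per = 15, sep = 9)
  models <- small_models()
  rep <- evaluate_models(tc$X, tc$y, scheme = cv_scheme(2, 3, seed = 5),
                         models = models)
  expect_true(all(rep$value >= 0 & rep$value <= 1))
  expect_true(all(rep$lower <= rep$value + 1e-12 & rep$value <= rep$upper + 1e-12))
  # perfectly separable: tree models at (or next to) ceiling
  for (mod in c("RF", "ETC")) {
    acc <- rep$value[rep$model == mod & rep$metric == "accuracy"]
    auc <- rep$value[rep$model == mod & rep$metric == "auc_macro_ovr"]
    expect_gte(acc, 0.97)
    expect_gte(auc, 0.99)
  }
  # metric oracle recomputed from the emitted out-of-fold predictions
  cp <- attr(rep, "predictions")
  P <- cp$repeats[[1]]$prob$NB
  pred <- cp$repeats[[1]]$pred$NB
  y <- tc$y
  acc <- mean(pred == y)
  prec <- sapply(cp$classes, function(k) {
    tp <- sum(pred == k & y == k); fp <- sum(pred == k & y != k)
    if (tp + fp == 0) 0 else tp / (tp + fp)
  })
  recall <- sapply(cp$classes, function(k) sum(pred == k & y == k) / sum(y == k))
  f1 <- ifelse(prec + recall == 0, 0, 2 * prec * recall / (prec + recall))
  scores <- attr(rep, "rep_scores")$NB[1, ]
  expect_equal(unname(scores["accuracy"]), acc, tolerance = 1e-12)
  expect_equal(unname(scores["precision_macro"]), mean(prec), tolerance = 1e-12)
  expect_equal(unname(scores["recall_micro"]), acc, tolerance = 1e-12)
  expect_equal(unname(scores["f1_macro"]), mean(f1), tolerance = 1e-12)

  # shuffled labels: accuracy near 1/3, AUC near 1/2
  set.seed(77)
  ysh <- sample(tc$y)
  rep0 <- evaluate_models(tc$X, ysh, scheme = cv_scheme(3, 3, seed = 5),
                          models = models["NB"])
  expect_lt(abs(rep0$value[rep0$metric == "accuracy"] - 1 / 3), 0.15)
  expect_lt(abs(rep0$value[rep0$metric == "auc_macro_ovr"] - 0.5), 0.12)
})

test_that("metrics are invariant to feature order and class renaming", {
  tc <- toy_classes(n_per = 12, sep = 2, seed = 9)
  models <- small_models()
  r1 <- evaluate_models(tc$X, tc$y, scheme = cv_scheme(1, 3, seed = 2),
                        models = models)
  r2 <- evaluate_models(tc$X[, rev(colnames(tc$X))], tc$y,
                        scheme = cv_scheme(1, 3, seed = 2), models = models)
  expect_equal(r1$value, r2$value, tolerance = 1e-12)
  y2 <- c(CTRL = "g_ctrl", DLP = "g_dlp", AT = "g_at")[tc$y]
  r3 <- evaluate_models(tc$X, y2, scheme = cv_scheme(1, 3, seed = 2),
                        models = models)
  expect_equal(r1$value, r3$value, tolerance = 1e-12)
})

test_that("permutation test follows the add-one formula and a chance null", {
  tc <- toy_classes(n_per = 10, sep = 5, seed = 3)
  pt <- permutation_test(tc$X, tc$y, model_spec("NB"),
                         scheme = cv_scheme(1, 3, seed = 4),
                         n_shuffles = 30, seed = 8)
  expect_equal(pt$p_value, (1 + sum(pt$null_auc >= pt$observed)) / 31)
  expect_gte(pt$p_value, 1 / 31)
  expect_gt(pt$observed, 0.95)          # separable data
  expect_lt(abs(pt$mean_null - 0.5), 0.08)
  # n_shuffles = 1 and null below observed -> p = 1/2
  pt1 <- permutation_test(tc$X, tc$y, model_spec("NB"),
                          scheme = cv_scheme(1, 3, seed = 4),
                          n_shuffles = 1, seed = 8)
  if (pt1$null_auc < pt1$observed) expect_equal(pt1$p_value, 0.5)
  expect_error(permutation_test(tc$X, rep("AT", length(tc$y)),
                                model_spec("NB")), "single-class")
})

test_that("consensus importance ranks an informative feature first", {
  set.seed(19)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, sprintf("f%02d", 1:8)))
  y <- rep(c("CTRL", "DLP", "AT"), each = 20)
  X[y == "AT", 4] <- X[y == "AT", 4] + 4
  X[y == "DLP", 4] <- X[y == "DLP", 4] - 4
  imp <- consensus_importance(X, y, models = small_models(),
                              scheme = cv_scheme(1, 3, seed = 6))
  expect_identical(imp$feature[1], "f04")
  # per-model normalized importances sum to 1 over features
  for (mod in model_names())
    expect_equal(sum(imp[[mod]]), 1, tolerance = 1e-9)
  # attribution flag adds a column without altering the consensus order
  imp2 <- consensus_importance(X, y, models = small_models(),
                               scheme = cv_scheme(1, 3, seed = 6),
                               include_attribution = TRUE)
  expect_identical(imp2$feature, imp$feature)
  expect_true("attribution" %in% names(imp2))
})
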