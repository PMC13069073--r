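test_that("a lone signal feature is flagged within a fold", {
  set.seed(41)
  n <- 60
  X <- matrix(rnorm(n * 31), n, 31,
              dimnames = list(NULL, c("signal", sprintf("noise%02d", 1:30))))
  y <- rep(c("CTRL", "DLP", "AT"), each = 20)
  X[y == "AT", "signal"] <- X[y == "AT", "signal"] + 3
  Xs <- apply_standardizer(fit_standardizer(X), X)
  res <- bootstrap_fold_selection(Xs, y, models = small_models(),
                                  n_bootstrap = 10, step_fraction = 0.25,
                                  seed = 2)
  expect_true(res$flag[["signal"]])
  expect_equal(res$boot_freq[["signal"]], 1)
  # inclusive boundary: retain_fraction = 1 still flags an always-selected one
  res2 <- bootstrap_fold_selection(Xs, y, models = small_models(),
                                   n_bootstrap = 5, retain_fraction = 1.0,
                                   step_fraction = 0.25, seed = 2)
  expect_true(res2$flag[["signal"]])
})

test_that("fold selection uses only the training samples it was given", {
  set.seed(43)
  X <- matrix(rnorm(45 * 10), 45, 10,
              dimnames = list(NULL, sprintf("f%02d", 1:10)))
  y <- rep(c("CTRL", "DLP", "AT"), each = 15)
  train <- c(1:10, 16:25, 31:40)
  Xs <- apply_standardizer(fit_standardizer(X[train, ]), X[train, ])
  r1 <- bootstrap_fold_selection(Xs, y[train], models = small_models(),
                                 n_bootstrap = 5, step_fraction = 0.25, seed = 3)
  # mutating held-out rows cannot touch the fold's flags
  X2 <- X; X2[-train, ] <- X2[-train, ] + 1000
  Xs2 <- apply_standardizer(fit_standardizer(X2[train, ]), X2[train, ])
  r2 <- bootstrap_fold_selection(Xs2, y[train], models = small_models(),
                                 n_bootstrap = 5, step_fraction = 0.25, seed = 3)
  expect_identical(r1$flag, r2$flag)
  expect_identical(r1$boot_freq, r2$boot_freq)
})

test_that("consensus selection recovers signal, is monotone and deterministic", {
  set.seed(47)
  n <- 75
  X <- matrix(rnorm(n * 24), n, 24,
              dimnames = list(NULL, c("sigA", "sigB", sprintf("n%02d", 1:22))))
  y <- rep(c("CTRL", "DLP", "AT"), each = 25)
  X[y == "AT", "sigA"] <- X[y == "AT", "sigA"] + 3
  X[y == "DLP", "sigB"] <- X[y == "DLP", "sigB"] - 3
  panel <- select_consensus_features(X, y, scheme = cv_scheme(1, 3, seed = 9),
                                     n_bootstrap = 8, models = small_models(),
                                     step_fraction = 0.25, seed = 9)
  expect_true(all(c("sigA", "sigB") %in% panel$feature))
  expect_true(all(panel$fold_freq >= 0.20))
  # determinism
  panel2 <- select_consensus_features(X, y, scheme = cv_scheme(1, 3, seed = 9),
                                      n_bootstrap = 8, models = small_models(),
                                      step_fraction = 0.25, seed = 9)
  expect_identical(as.data.frame(panel), as.data.frame(panel2))
  # raising the fold threshold never enlarges the panel
  panel_hi <- select_consensus_features(X, y, scheme = cv_scheme(1, 3, seed = 9),
                                        fold_threshold = 0.67, n_bootstrap = 8,
                                        models = small_models(),
                                        step_fraction = 0.25, seed = 9)
  expect_true(all(panel_hi$feature %in% panel$feature))
  expect_lte(nrow(panel_hi), nrow(panel))
})

test_that("duplicated signal columns collapse to one representative", {
  set.seed(53)
  n <- 60
  base <- rnorm(n)
  y <- rep(c("CTRL", "DLP", "AT"), each = 20)
  sig <- base + ifelse(y == "AT", 3, 0)
  X <- cbind(sig_one = sig, sig_two = sig,
             matrix(rnorm(n * 12), n, 12,
                    dimnames = list(NULL, sprintf("n%02d", 1:12))))
  panel <- select_consensus_features(X, y, scheme = cv_scheme(1, 3, seed = 1),
                                     n_bootstrap = 8, models = small_models(),
                                     step_fraction = 0.25, seed = 1)
  kept <- intersect(c("sig_one", "sig_two"), panel$feature)
  expect_length(kept, 1)
  dropped <- setdiff(c("sig_one", "sig_two"), kept)
  expect_true(grepl(dropped, panel$cluster_members[panel$feature == kept],
                    fixed = TRUE))
})

test_that("dedup_correlated applies single linkage with the stated tie-breaks", {
  mkpanel <- function(features, fold, boot) {
    p <- data.frame(feature = features, fold_freq = fold, boot_freq = boot,
                    cluster_members = "", stringsAsFactors = FALSE)
    class(p) <- c("feature_panel", class(p))
    p
  }
  # identical pair: higher fold frequency wins
  x <- rnorm(20)
  X <- cbind(a = x, b = x)
  out <- dedup_correlated(mkpanel(c("a", "b"), c(0.8, 0.4), c(0.5, 0.5)), X)
  expect_identical(out$feature, "a")
  expect_identical(out$cluster_members, "b")

  # pair below the threshold is kept whole (strict grouping at >= 0.85)
  r1 <- 1:5
  r2 <- c(3, 1, 2, 5, 4)           # Spearman rho = 0.6 by construction
  stopifnot(abs(cor(r1, r2, method = "spearman") - 0.6) < 1e-12)
  X2 <- cbind(a = r1, b = r2)
  out2 <- dedup_correlated(mkpanel(c("a", "b"), c(0.8, 0.4), c(0.5, 0.5)), X2,
                           rho_threshold = 0.85)
  expect_setequal(out2$feature, c("a", "b"))
  # the same pair is grouped once the threshold drops below its correlation
  out3 <- dedup_correlated(mkpanel(c("a", "b"), c(0.8, 0.4), c(0.5, 0.5)), X2,
                           rho_threshold = 0.55)
  expect_identical(out3$feature, "a")
  # the grouping boundary itself is inclusive (exact rho = 1 at threshold 1)
  X4 <- cbind(a = 1:6, b = 2 * (1:6))
  out3b <- dedup_correlated(mkpanel(c("a", "b"), c(0.8, 0.4), c(0.5, 0.5)), X4,
                            rho_threshold = 1)
  expect_identical(out3b$feature, "a")

  # chain A-B, B-C strong, A-C weak: one cluster, one representative
  set.seed(59)
  n <- 200
  f <- rnorm(n)
  A <- f + rnorm(n, sd = 0.45)
  B <- f
  C <- f + rnorm(n, sd = 0.45)
  X3 <- cbind(A = A, B = B, C = C)
  rho <- cor(X3, method = "spearman")
  # premise: both edges reach 0.85, the A-C edge does not
  stopifnot(rho["A", "B"] >= 0.85, rho["B", "C"] >= 0.85, rho["A", "C"] < 0.85)
  out4 <- dedup_correlated(mkpanel(c("A", "B", "C"), c(0.9, 0.5, 0.4),
                                   c(0.5, 0.5, 0.5)), X3)
  expect_identical(out4$feature, "A")
  expect_setequal(strsplit(out4$cluster_members, ";")[[1]], c("B", "C"))
  # anti-correlated duplicates are grouped too (|rho|)
  X5 <- cbind(u = x, v = -x)
  out5 <- dedup_correlated(mkpanel(c("u", "v"), c(0.9, 0.2), c(0.5, 0.5)), X5)
  expect_identical(out5$feature, "u")
})
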