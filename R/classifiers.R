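#' The five classifier families
#'
#' `build_classifiers` returns the benchmark bank: Gaussian naive Bayes
#' (NB), linear support-vector machine with sigmoid probability calibration
#' (LSVM), random forest (RF), extremely randomized trees (ETC) and SAMME
#' AdaBoost on decision stumps (AB). Every family is exposed behind one
#' probabilistic interface: [fit_model()] then [predict_prob()], which
#' yields per-sample class-probability vectors summing to 1.
#'
#' @param config named list of hyperparameter overrides per model, e.g.
#'   `list(RF = list(n_trees = 50))`. Recognised fields: `n_trees`
#'   (RF/ETC), `max_depth`, `min_leaf`, `n_stumps` (AB), `C` (LSVM),
#'   `var_eps` (NB).
#' @param names which families to build (default all five).
#' @return list of `model_spec` objects, one per family.
#' @export
build_classifiers <- function(config = list(), names = model_names()) {
  unknown <- setdiff(names, model_names())
  if (length(unknown) > 0)
    stop("unknown model name(s): ", paste(unknown, collapse = ", "))
  lapply(setNames(names, names), function(nm) model_spec(nm, config[[nm]]))
}

#' @rdname build_classifiers
#' @export
model_names <- function() c("NB", "LSVM", "RF", "ETC", "AB")

#' @rdname build_classifiers
#' @param name one of `"NB"`, `"LSVM"`, `"RF"`, `"ETC"`, `"AB"`.
#' @param hyper named list of hyperparameter overrides.
#' @export
model_spec <- function(name, hyper = NULL) {
  if (!name %in% model_names()) stop("unknown model name: ", name)
  defaults <- switch(name,
    NB   = list(var_eps = 1e-9),
    LSVM = list(C = 1),
    RF   = list(n_trees = 100L, max_depth = 25L, min_leaf = 1L),
    ETC  = list(n_trees = 100L, max_depth = 25L, min_leaf = 1L),
    AB   = list(n_stumps = 50L))
  if (!is.null(hyper)) defaults[names(hyper)] <- hyper
  structure(list(name = name, hyper = defaults,
                 importance_mode = switch(name, NB = "fallback_F",
                                          LSVM = "coefficient", "impurity"),
                 probability_mode = if (name == "LSVM") "calibrated" else "native"),
            class = "model_spec")
}

# Class levels in order of first appearance: keeps argmax tie-breaking
# invariant under any renaming bijection of the labels.
class_levels <- function(y) unique(as.character(y))

#' Fit one classifier
#'
#' @param spec a `model_spec`.
#' @param X numeric matrix, samples x features (column names required for
#'   importance reporting).
#' @param y class labels (>= 2 classes present).
#' @param seed RNG seed; with the same seed, fitting is deterministic.
#' @return a fitted `ps_fit` object.
#' @export
fit_model <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  # canonical column order: fits are invariant to the caller's feature order
  if (!is.null(colnames(X))) X <- X[, order(colnames(X)), drop = FALSE]
  classes <- class_levels(y)
  if (length(classes) < 2) stop("fit_model: need >= 2 classes")
  y0 <- match(as.character(y), classes) - 1L
  K <- length(classes)
  h <- spec$hyper
  fit <- with_seed(seed, switch(spec$name,
    NB = fit_gnb(X, y0, K, h$var_eps),
    LSVM = fit_lsvm_ovr(X, y0, K, h$C),
    RF = .cpp_forest_fit(X, y0, K, h$n_trees,
                         max(1L, floor(sqrt(ncol(X)))), h$min_leaf,
                         h$max_depth, TRUE, FALSE),
    ETC = .cpp_forest_fit(X, y0, K, h$n_trees,
                          max(1L, floor(sqrt(ncol(X)))), h$min_leaf,
                          h$max_depth, FALSE, TRUE),
    AB = .cpp_ada_fit(X, y0, K, h$n_stumps)))
  structure(list(spec = spec, classes = classes, fit = fit,
                 features = colnames(X)), class = "ps_fit")
}

#' Class-probability predictions
#'
#' @param object a `ps_fit`.
#' @param X numeric matrix with the same feature columns used at fit time.
#' @return matrix samples x classes of probabilities (rows sum to 1).
#' @export
predict_prob <- function(object, X) {
  stopifnot(inherits(object, "ps_fit"))
  X <- as.matrix(X)
  if (!is.null(object$features) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$features))
    X <- X[, object$features, drop = FALSE]
  P <- switch(object$spec$name,
    NB = predict_gnb(object$fit, X),
    LSVM = predict_lsvm_ovr(object$fit, X),
    RF = .cpp_forest_predict(object$fit, X),
    ETC = .cpp_forest_predict(object$fit, X),
    AB = .cpp_ada_predict(object$fit, X))
  colnames(P) <- object$classes
  rownames(P) <- rownames(X)
  P
}

#' Predicted class labels (argmax probability)
#' @inheritParams predict_prob
#' @return character vector of predicted classes.
#' @export
predict_class <- function(object, X) {
  P <- predict_prob(object, X)
  colnames(P)[max.col(P, ties.method = "first")]
}

#' Per-feature importance of a fitted model
#'
#' Native impurity importance for the tree families (RF, ETC, AB), mean
#' absolute one-vs-rest coefficient for LSVM, `NULL` for NB (callers fall
#' back to univariate F statistics).
#'
#' @param object a `ps_fit`.
#' @return named numeric vector, or `NULL` for NB.
#' @export
model_importance <- function(object) {
  stopifnot(inherits(object, "ps_fit"))
  imp <- switch(object$spec$name,
    NB = return(NULL),
    LSVM = colMeans(abs(object$fit$W)),
    RF = as.numeric(object$fit$importance),
    ETC = as.numeric(object$fit$importance),
    AB = as.numeric(object$fit$importance))
  names(imp) <- object$features
  imp
}

# ---- Gaussian naive Bayes ----------------------------------------------

fit_gnb <- function(X, y0, K, var_eps) {
  p <- ncol(X)
  mu <- matrix(0, K, p)
  v <- matrix(0, K, p)
  prior <- numeric(K)
  for (k in seq_len(K)) {
    idx <- y0 == (k - 1L)
    prior[k] <- mean(idx)
    mu[k, ] <- colMeans(X[idx, , drop = FALSE])
    v[k, ] <- apply(X[idx, , drop = FALSE], 2, var)
  }
  v[!is.finite(v)] <- 0
  floor_v <- var_eps * max(v, 1e-12)
  v <- pmax(v, floor_v)
  list(mu = mu, v = v, prior = prior, K = K)
}

predict_gnb <- function(fit, X) {
  n <- nrow(X); K <- fit$K
  ll <- matrix(0, n, K)
  for (k in seq_len(K)) {
    d <- sweep(X, 2, fit$mu[k, ], `-`)
    ll[, k] <- log(fit$prior[k]) -
      0.5 * rowSums(sweep(d^2, 2, fit$v[k, ], `/`)) -
      0.5 * sum(log(2 * pi * fit$v[k, ]))
  }
  m <- apply(ll, 1, max)
  P <- exp(ll - m)
  P / rowSums(P)
}

# ---- Linear SVM (squared hinge, L2) with sigmoid calibration ------------

fit_lsvm_binary <- function(X, yy, C) {
  p <- ncol(X)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    m <- 1 - yy * (drop(X %*% w) + b)
    0.5 * sum(w^2) + C * sum(pmax(m, 0)^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    m <- 1 - yy * (drop(X %*% w) + b)
    act <- m > 0
    gy <- -2 * C * (yy * m)[act]
    c(w + drop(crossprod(X[act, , drop = FALSE], gy)), sum(gy))
  }
  res <- optim(numeric(p + 1), obj, grad, method = "L-BFGS-B",
               control = list(maxit = 200))
  list(w = res$par[seq_len(p)], b = res$par[p + 1])
}

# Platt-style sigmoid on training decision values, with the regularized
# targets from Platt (1999) to tame perfect separation.
fit_platt <- function(f, y01) {
  np <- sum(y01 == 1); nn <- sum(y01 == 0)
  t_hi <- (np + 1) / (np + 2); t_lo <- 1 / (nn + 2)
  tt <- ifelse(y01 == 1, t_hi, t_lo)
  nll <- function(par) {
    z <- par[1] * f + par[2]
    # cross-entropy against soft targets, numerically stable
    sum(log1p(exp(-abs(z))) + pmax(z, 0) - tt * z)
  }
  res <- optim(c(-1, 0), nll, method = "BFGS", control = list(maxit = 100))
  res$par
}

fit_lsvm_ovr <- function(X, y0, K, C) {
  p <- ncol(X)
  W <- matrix(0, K, p)
  b <- numeric(K)
  platt <- matrix(0, K, 2)
  for (k in seq_len(K)) {
    yy <- ifelse(y0 == (k - 1L), 1, -1)
    svc <- fit_lsvm_binary(X, yy, C)
    W[k, ] <- svc$w; b[k] <- svc$b
    f <- drop(X %*% svc$w) + svc$b
    platt[k, ] <- fit_platt(f, as.integer(yy == 1))
  }
  list(W = W, b = b, platt = platt, K = K)
}

predict_lsvm_ovr <- function(fit, X) {
  K <- fit$K
  Fm <- X %*% t(fit$W)
  Fm <- sweep(Fm, 2, fit$b, `+`)
  P <- matrix(0, nrow(X), K)
  for (k in seq_len(K))
    P[, k] <- plogis(fit$platt[k, 1] * Fm[, k] + fit$platt[k, 2])
  P <- pmax(P, 1e-12)
  P / rowSums(P)
}

#' Univariate one-way ANOVA F statistics
#'
#' Per-feature F statistic of the between-group vs within-group variance
#' ratio; the fallback feature-ranking criterion for models exposing
#' neither coefficients nor impurity importances.
#'
#' @param X numeric matrix, samples x features.
#' @param y class labels.
#' @return named numeric vector of F statistics (0 where undefined).
#' @export
f_statistic <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- unique(y)
  n <- nrow(X); K <- length(classes)
  gm <- colMeans(X)
  ssb <- numeric(ncol(X)); ssw <- numeric(ncol(X))
  for (cls in classes) {
    idx <- y == cls
    m <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + sum(idx) * (m - gm)^2
    ssw <- ssw + colSums(sweep(X[idx, , drop = FALSE], 2, m, `-`)^2)
  }
  f <- (ssb / (K - 1)) / (ssw / (n - K))
  f[!is.finite(f)] <- 0
  names(f) <- colnames(X)
  f
}
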