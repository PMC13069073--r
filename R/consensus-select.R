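# Recursive feature elimination on one model family: drop the lowest-ranked
# `step_fraction` of remaining features per iteration until `n_target`
# remain. Ranking comes from |coefficients| (LSVM), impurity importances
# (RF/ETC/AB) or, for families exposing neither (NB), the univariate F
# statistic (a single ranking, no refits needed).
rfe_select <- function(spec, X, y, n_target, step_fraction = 0.10, seed = 1L) {
  feats <- colnames(X)
  if (length(feats) <= n_target) return(feats)
  if (spec$importance_mode == "fallback_F") {
    f <- f_statistic(X, y)
    return(names(sort(f, decreasing = TRUE))[seq_len(n_target)])
  }
  it <- 0L
  while (length(feats) > n_target) {
    it <- it + 1L
    fit <- fit_model(spec, X[, feats, drop = FALSE], y,
                     seed = child_seed(seed, it))
    imp <- abs(model_importance(fit))
    n_drop <- min(max(1L, ceiling(step_fraction * length(feats))),
                  length(feats) - n_target)
    # ties at the bottom broken by name for determinism
    ord <- order(imp, rank(names(imp)))
    feats <- setdiff(feats, names(imp)[ord[seq_len(n_drop)]])
  }
  feats
}

# Stratified bootstrap resample: per class, sample its indices with
# replacement, preserving class counts. Every class is present by
# construction; the redraw guard covers pathological label inputs.
stratified_bootstrap <- function(y, max_retries = 10L) {
  for (i in seq_len(max_retries)) {
    idx <- unlist(lapply(unique(y), function(cls) {
      w <- which(y == cls)
      w[sample.int(length(w), length(w), replace = TRUE)]
    }), use.names = FALSE)
    if (length(unique(y[idx])) == length(unique(y))) return(idx)
  }
  stop("bootstrap resample kept missing a class after retries")
}

#' Bootstrap-consensus feature selection inside one training fold
#'
#' For each of `n_bootstrap` stratified bootstrap resamples of the training
#' data, one selector per model family keeps the top `target_fraction` of
#' features (recursive feature elimination for models exposing coefficient
#' or impurity rankings, univariate F-test ranking as fallback). A feature
#' counts as selected in a bootstrap when chosen by at least 3 of the 5
#' selectors; the fold-level flag is set when a feature's bootstrap
#' selection frequency reaches `retain_fraction` (inclusive).
#'
#' @param X_train standardized training matrix (samples x features).
#' @param y_train training labels (>= 2 classes).
#' @param models classifier bank (list of `model_spec`).
#' @param n_bootstrap bootstrap resamples per fold (default 50).
#' @param retain_fraction within-fold retention threshold (default 0.60,
#'   inclusive).
#' @param target_fraction fraction of features each selector keeps.
#' @param min_selectors per-bootstrap consensus count (default 3 of 5).
#' @param step_fraction RFE per-iteration drop fraction.
#' @param seed RNG seed.
#' @return list with `flag` (logical per feature) and `boot_freq`
#'   (per-feature bootstrap selection frequency).
#' @export
bootstrap_fold_selection <- function(X_train, y_train,
                                     models = build_classifiers(),
                                     n_bootstrap = 50L,
                                     retain_fraction = 0.60,
                                     target_fraction = 0.25,
                                     min_selectors = 3L,
                                     step_fraction = 0.10,
                                     seed = 1L) {
  X_train <- as.matrix(X_train)
  y_train <- as.character(y_train)
  if (length(unique(y_train)) < 2) stop("need >= 2 classes in the fold")
  feats <- colnames(X_train)
  p <- length(feats)
  n_target <- max(1L, ceiling(target_fraction * p))
  counts <- setNames(numeric(p), feats)
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      idx <- stratified_bootstrap(y_train)
      Xb <- X_train[idx, , drop = FALSE]
      yb <- y_train[idx]
      votes <- setNames(integer(p), feats)
      for (mi in seq_along(models)) {
        sel <- rfe_select(models[[mi]], Xb, yb, n_target, step_fraction,
                          seed = child_seed(seed, b * 10L + mi))
        votes[sel] <- votes[sel] + 1L
      }
      counts <- counts + (votes >= min_selectors)
    }
  })
  boot_freq <- counts / n_bootstrap
  list(flag = boot_freq >= retain_fraction, boot_freq = boot_freq)
}

#' Consensus feature selection over repeated stratified CV
#'
#' Runs [bootstrap_fold_selection()] in every training fold of the
#' `n_repeats x n_folds` scheme (15 folds at the reference 3x5 setting),
#' retains features flagged in at least `fold_threshold` of folds
#' (inclusive), then collapses correlated clusters with
#' [dedup_correlated()]. Standardization is fitted inside each training
#' fold; held-out samples never influence selection.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param scheme a [cv_scheme()] (reference setting: 3 repeats, 5 folds).
#' @param fold_threshold fold-level consensus threshold (default 0.20).
#' @param rho_threshold Spearman dedup threshold (default 0.85).
#' @inheritParams bootstrap_fold_selection
#' @return a `feature_panel` data.frame: `feature`, `fold_freq`,
#'   `boot_freq`, `cluster_members`, ordered by fold frequency (desc),
#'   ties by mean bootstrap frequency then name.
#' @export
select_consensus_features <- function(X, y, scheme = cv_scheme(3, 5),
                                      fold_threshold = 0.20,
                                      n_bootstrap = 50L,
                                      target_fraction = 0.25,
                                      rho_threshold = 0.85,
                                      models = build_classifiers(),
                                      min_selectors = 3L,
                                      step_fraction = 0.10,
                                      seed = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  seed <- if (is.null(seed)) scheme$seed else seed
  folds <- make_folds(y, scheme, seed)
  feats <- colnames(X)
  flag_sum <- setNames(numeric(length(feats)), feats)
  freq_sum <- setNames(numeric(length(feats)), feats)
  n_folds_total <- scheme$n_repeats * scheme$n_folds
  for (r in seq_len(scheme$n_repeats)) {
    for (f in seq_len(scheme$n_folds)) {
      train <- which(folds[[r]] != f)
      st <- fit_standardizer(X, train)
      Xtr <- apply_standardizer(st, X)[train, , drop = FALSE]
      res <- bootstrap_fold_selection(
        Xtr, y[train], models = models, n_bootstrap = n_bootstrap,
        target_fraction = target_fraction, min_selectors = min_selectors,
        step_fraction = step_fraction,
        seed = child_seed(seed, r * 100L + f))
      flag_sum <- flag_sum + res$flag
      freq_sum <- freq_sum + res$boot_freq
    }
  }
  fold_freq <- flag_sum / n_folds_total
  boot_freq <- freq_sum / n_folds_total
  keep <- names(fold_freq)[fold_freq >= fold_threshold]
  panel <- data.frame(feature = keep,
                      fold_freq = unname(fold_freq[keep]),
                      boot_freq = unname(boot_freq[keep]),
                      cluster_members = "",
                      stringsAsFactors = FALSE)
  panel <- panel_order(panel)
  class(panel) <- c("feature_panel", class(panel))
  dedup_correlated(panel, X, rho_threshold = rho_threshold)
}

panel_order <- function(panel) {
  panel[order(-panel$fold_freq, -panel$boot_freq, panel$feature), ,
        drop = FALSE]
}

#' Collapse correlated panel features
#'
#' Groups panel features whose pairwise |Spearman rho| on the reference
#' data reaches `rho_threshold`, by single linkage, and keeps one
#' representative per cluster: the feature with the highest fold-selection
#' frequency (ties: higher mean bootstrap frequency, then lexicographic).
#' Absorbed members are recorded in the representative's
#' `cluster_members`.
#'
#' @param panel a `feature_panel`.
#' @param X reference data matrix holding the panel features.
#' @param rho_threshold inclusive |Spearman| grouping threshold.
#' @return the deduplicated `feature_panel`.
#' @export
dedup_correlated <- function(panel, X, rho_threshold = 0.85) {
  feats <- panel$feature
  missing <- setdiff(feats, colnames(X))
  if (length(missing) > 0)
    stop("panel feature(s) absent from X: ", paste(missing, collapse = ", "))
  if (length(feats) < 2) return(panel)
  rho <- suppressWarnings(cor(as.matrix(X)[, feats, drop = FALSE],
                              method = "spearman"))
  rho[!is.finite(rho)] <- 0
  adj <- abs(rho) >= rho_threshold
  diag(adj) <- FALSE
  # connected components = single-linkage clusters at the threshold
  comp <- rep(NA_integer_, length(feats))
  cid <- 0L
  for (i in seq_along(feats)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  rows <- lapply(split(seq_along(feats), comp), function(members) {
    sub <- panel[members, , drop = FALSE]
    sub <- panel_order(sub)
    rep_row <- sub[1, , drop = FALSE]
    others <- setdiff(sub$feature, rep_row$feature)
    prior <- rep_row$cluster_members
    all_members <- c(if (nzchar(prior)) strsplit(prior, ";")[[1]], others)
    rep_row$cluster_members <- paste(all_members, collapse = ";")
    rep_row
  })
  out <- do.call(rbind, rows)
  out <- panel_order(out)
  rownames(out) <- NULL
  class(out) <- c("feature_panel", class(out))
  out
}

#' Serialize a feature panel
#' @param panel a `feature_panel`.
#' @param path output path (`.csv` or `.json` by extension).
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(panel), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  }
  invisible(path)
}
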