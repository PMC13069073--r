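#' Binary ROC with Youden cutoff
#'
#' AUC is the rank (pair-concordance) statistic with ties counted 1/2,
#' oriented "higher value = positive". The cutoff maximizes the Youden
#' index J = sensitivity + specificity - 1 over thresholds placed midway
#' between adjacent distinct values (a sample is called positive when its
#' value exceeds the cutoff); ties in J are broken toward higher
#' sensitivity (the lower cutoff).
#'
#' @param values numeric marker values, finite.
#' @param labels binary labels; either logical (TRUE = positive) or a
#'   vector with exactly two levels plus `positive` naming the positive one.
#' @param positive positive class (required for non-logical labels).
#' @return a `roc_result` list: `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `youden_j`, `n_pos`, `n_neg`.
#' @export
binary_auc <- function(values, labels, positive = NULL) {
  if (!all(is.finite(values))) stop("binary_auc: values must be finite")
  if (is.logical(labels)) {
    pos <- labels
  } else {
    lv <- unique(as.character(labels))
    if (length(lv) != 2 && is.null(positive))
      stop("binary_auc: labels must be binary (or give `positive`)")
    if (is.null(positive)) positive <- lv[2]
    pos <- as.character(labels) == positive
  }
  if (sum(pos) == 0 || sum(!pos) == 0)
    stop("binary_auc: both classes must be present")
  auc <- auc_rank(values, pos)

  sv <- sort(unique(values))
  if (length(sv) < 2) {
    cutoff <- NA_real_; sens <- NA_real_; spec <- NA_real_; j <- NA_real_
  } else {
    cuts <- (sv[-1] + sv[-length(sv)]) / 2
    best_j <- -Inf; cutoff <- NA_real_; sens <- NA_real_; spec <- NA_real_
    for (ct in cuts) {  # ascending: first max wins -> higher sensitivity
      s <- sum(values[pos] > ct) / sum(pos)
      sp <- sum(values[!pos] <= ct) / sum(!pos)
      if (s + sp - 1 > best_j + 1e-12) {
        best_j <- s + sp - 1; cutoff <- ct; sens <- s; spec <- sp
      }
    }
    j <- best_j
  }
  structure(list(auc = auc, cutoff = cutoff, sensitivity = sens,
                 specificity = spec, youden_j = j,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc> AUC %.3f, Youden cutoff %.4g (sens %.2f, spec %.2f)\n",
              x$auc, x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' ROC coordinate table
#'
#' Full (fpr, tpr, threshold) trace for plotting, thresholds descending.
#'
#' @inheritParams binary_auc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_coordinates <- function(values, labels, positive = NULL) {
  if (is.logical(labels)) pos <- labels
  else pos <- as.character(labels) == positive
  thr <- c(Inf, sort(unique(values), decreasing = TRUE))
  data.frame(threshold = thr,
             fpr = vapply(thr, function(t) mean(values[!pos] >= t), numeric(1)),
             tpr = vapply(thr, function(t) mean(values[pos] >= t), numeric(1)))
}

#' Dual-comparison AUC biomarker filter
#'
#' A candidate feature is retained iff its direction-agnostic AUC,
#' `max(AUC, 1 - AUC)`, strictly exceeds `threshold` in BOTH binary
#' comparisons AT-vs-DLP and AT-vs-CTRL. Orientation-free because panel
#' markers may be up- or down-regulated in the disease group.
#'
#' @param X samples x features matrix.
#' @param labels data.frame (`sample_id`, `group`) or group vector in row
#'   order; must contain all three groups.
#' @param candidate_features features to screen (default: all columns).
#' @param threshold strict AUC threshold (default 0.7).
#' @param positive_group disease group (default `"AT"`).
#' @param reference_groups the two comparator groups.
#' @return list with `retained` (character vector) and `results`
#'   (data.frame: feature, comparison, auc, auc_direction_free, cutoff,
#'   sensitivity, specificity, retained).
#' @export
filter_panel_by_auc <- function(X, labels, candidate_features = colnames(X),
                                threshold = 0.7, positive_group = "AT",
                                reference_groups = c("DLP", "CTRL")) {
  X <- as.matrix(X)
  grp <- resolve_groups(labels, rownames(X), nrow(X))
  need <- c(positive_group, reference_groups)
  if (!all(need %in% grp))
    stop("labels must contain all of: ", paste(need, collapse = ", "))
  missing <- setdiff(candidate_features, colnames(X))
  if (length(missing) > 0)
    stop("candidate feature(s) absent from X: ", paste(missing, collapse = ", "))
  rows <- list()
  retained <- character(0)
  for (feat in candidate_features) {
    dfree <- numeric(length(reference_groups))
    feat_rows <- list()
    for (gi in seq_along(reference_groups)) {
      ref <- reference_groups[gi]
      idx <- grp %in% c(positive_group, ref)
      roc <- binary_auc(X[idx, feat], grp[idx], positive = positive_group)
      dfree[gi] <- max(roc$auc, 1 - roc$auc)
      feat_rows[[gi]] <- data.frame(
        feature = feat,
        comparison = paste(positive_group, "vs", ref),
        auc = roc$auc, auc_direction_free = dfree[gi],
        cutoff = roc$cutoff, sensitivity = roc$sensitivity,
        specificity = roc$specificity, stringsAsFactors = FALSE)
    }
    keep <- all(dfree > threshold)
    if (keep) retained <- c(retained, feat)
    for (fr in feat_rows) {
      fr$retained <- keep
      rows[[length(rows) + 1]] <- fr
    }
  }
  list(retained = retained, results = do.call(rbind, rows),
       threshold = threshold)
}

#' Within-group Spearman correlation screen
#'
#' All pairwise Spearman correlations among features, computed within the
#' samples of one group; pairs with |R| strictly above `r_threshold` are
#' selected, each pair reported once, sorted by |R| descending. Constant
#' features yield undefined correlations: their pairs are reported with
#' `R = NA` and never selected.
#'
#' @param X samples x features matrix.
#' @param labels group labels (data.frame or vector, as elsewhere).
#' @param group the group to screen within (>= 3 samples).
#' @param r_threshold strict |R| threshold (default 0.6).
#' @param features columns to include (default all).
#' @return data.frame `feature_i`, `feature_j`, `R`, `selected`.
#' @export
spearman_screen <- function(X, labels, group, r_threshold = 0.6,
                            features = colnames(X)) {
  X <- as.matrix(X)
  grp <- resolve_groups(labels, rownames(X), nrow(X))
  idx <- which(grp == group)
  if (length(idx) < 3) stop("need >= 3 samples in group ", group)
  sub <- X[idx, features, drop = FALSE]
  constant <- apply(sub, 2, function(v) length(unique(v[!is.na(v)])) < 2)
  R <- suppressWarnings(cor(sub, method = "spearman",
                            use = "pairwise.complete.obs"))
  R[constant, ] <- NA; R[, constant] <- NA
  pairs <- which(upper.tri(R), arr.ind = TRUE)
  out <- data.frame(feature_i = features[pairs[, 1]],
                    feature_j = features[pairs[, 2]],
                    R = R[pairs], stringsAsFactors = FALSE)
  out$selected <- !is.na(out$R) & abs(out$R) > r_threshold
  out <- out[order(-abs(out$R), out$feature_i, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Dunn's post-hoc pairwise z tests on ranks (tie-corrected), Bonferroni.
dunn_posthoc <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  groups <- as.character(groups)
  gl <- unique(groups)
  mean_ranks <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  combs <- utils::combn(gl, 2)
  n_pairs <- ncol(combs)
  rows <- lapply(seq_len(n_pairs), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    data.frame(group_a = a, group_b = b, z = z,
               p = 2 * pnorm(-abs(z)),
               p_adj = min(1, 2 * pnorm(-abs(z)) * n_pairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Baseline group-comparison tests
#'
#' Continuous variables: tie-corrected Kruskal-Wallis H with Dunn pairwise
#' z tests as post hoc (Bonferroni-adjusted). Categorical variables:
#' Pearson chi-square on the contingency table. Two-sided p-values
#' throughout.
#'
#' @param x for `type = "continuous"`, a numeric vector (paired with
#'   `groups`); for `type = "categorical"`, a contingency table / matrix
#'   (groups x categories).
#' @param groups group labels for the continuous case.
#' @param type test family.
#' @return a list: for continuous, `statistic` (H), `df`, `p_value` and
#'   `posthoc` (Dunn table); for categorical, `statistic` (X-squared),
#'   `df`, `p_value`.
#' @export
group_tests <- function(x, groups = NULL,
                        type = c("continuous", "categorical")) {
  type <- match.arg(type)
  if (type == "continuous") {
    stopifnot(!is.null(groups), length(x) == length(groups))
    keep <- !is.na(x) & !is.na(groups)
    x <- x[keep]; groups <- as.character(groups)[keep]
    if (any(table(groups) == 0) || length(unique(groups)) < 2)
      stop("need >= 2 non-empty groups")
    kw <- kruskal.test(x, factor(groups))
    list(test = "kruskal-wallis",
         statistic = unname(kw$statistic), df = unname(kw$parameter),
         p_value = kw$p.value,
         posthoc = dunn_posthoc(x, groups))
  } else {
    tab <- as.matrix(x)
    if (any(rowSums(tab) == 0) || any(dim(tab) < 2))
      stop("contingency table needs >= 2 non-empty rows and columns")
    ch <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(test = "chi-square",
         statistic = unname(ch$statistic), df = unname(ch$parameter),
         p_value = ch$p.value)
  }
}

#' Robust outlier flagging (optional, off by default in the pipeline)
#'
#' A documented stand-in for proprietary outlier detection: flags values
#' more than `k` median absolute deviations from the median. Flagging
#' only — nothing is removed unless the caller chooses to.
#'
#' @param x numeric vector.
#' @param k MAD multiplier (default 3.5, a conventional robust cut).
#' @return logical vector, TRUE = flagged.
#' @export
flag_outliers_mad <- function(x, k = 3.5) {
  med <- median(x, na.rm = TRUE)
  madv <- median(abs(x - med), na.rm = TRUE) * 1.4826
  if (!is.finite(madv) || madv == 0) return(rep(FALSE, length(x)))
  !is.na(x) & abs(x - med) / madv > k
}
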