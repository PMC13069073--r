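#' k-nearest-neighbour imputation of a clinical table
#'
#' Each missing cell is replaced by the inverse-distance-weighted mean of
#' the feature's values among the `k` nearest samples. Distance between two
#' samples is Euclidean over their mutually present features, rescaled by
#' the fraction of features used, i.e. `sqrt(sum(diff^2) * p / m)` with `m`
#' shared features of `p` total — so sparsely overlapping pairs are not
#' spuriously close. By default distances are computed on per-feature
#' standardized values (raw clinical units are incommensurable); the
#' imputed values themselves are on the original scale. A neighbour at
#' distance exactly 0 short-circuits the weighting: the mean of the
#' zero-distance duplicates is used.
#'
#' @param t a `clinical_table`; every sample needs >= 1 present feature and
#'   every feature >= k present samples.
#' @param k number of neighbours (default 5).
#' @param standardize_distances compute distances on standardized features.
#' @return the completed `clinical_table`.
#' @export
knn_impute <- function(t, k = 5L, standardize_distances = TRUE) {
  stopifnot(inherits(t, "clinical_table"))
  v <- t$values
  if (!anyNA(v)) return(t)
  n <- nrow(v); p <- ncol(v)
  present_per_sample <- rowSums(!is.na(v))
  if (any(present_per_sample < 1))
    stop("knn_impute: sample(s) with no present features: ",
         paste(rownames(v)[present_per_sample < 1], collapse = ", "))
  present_per_feature <- colSums(!is.na(v))
  short <- present_per_feature < k
  if (any(short))
    stop("knn_impute: feature(s) with fewer than k present samples: ",
         paste(colnames(v)[short], collapse = ", "))

  z <- v
  if (standardize_distances) {
    mu <- colMeans(v, na.rm = TRUE)
    s <- apply(v, 2, sd, na.rm = TRUE)
    s[!is.finite(s) | s == 0] <- 1
    z <- sweep(sweep(v, 2, mu, `-`), 2, s, `/`)
  }
  M <- !is.na(z)
  z0 <- z; z0[!M] <- 0
  Mn <- M * 1
  cnt <- Mn %*% t(Mn)
  sq <- z0^2
  d2 <- sq %*% t(Mn) + Mn %*% t(sq) - 2 * z0 %*% t(z0)
  d2[d2 < 0] <- 0                      # numerical fuzz
  d <- sqrt(d2 * p / pmax(cnt, 1))
  d[cnt == 0] <- Inf
  diag(d) <- Inf

  out <- v
  for (j in seq_len(p)) {
    miss <- which(is.na(v[, j]))
    if (length(miss) == 0) next
    donors <- which(!is.na(v[, j]))
    for (i in miss) {
      dd <- d[i, donors]
      ord <- order(dd)[seq_len(min(k, length(donors)))]
      nb <- donors[ord]
      dn <- dd[ord]
      if (any(dn == 0)) {
        out[i, j] <- mean(v[nb[dn == 0], j])
      } else if (all(!is.finite(dn))) {
        out[i, j] <- mean(v[donors, j])  # no overlap with anyone: feature mean
      } else {
        w <- 1 / dn[is.finite(dn)]
        out[i, j] <- sum(w * v[nb[is.finite(dn)], j]) / sum(w)
      }
    }
  }
  t$values <- out
  t
}

#' Leakage-safe feature standardizer
#'
#' `fit_standardizer` learns per-feature center (mean) and scale (SD) from
#' the training samples only; `apply_standardizer` transforms any table with
#' those frozen parameters, so held-out statistics can never leak into the
#' transform. Features with zero training variance are flagged and passed
#' through unchanged (center 0, scale 1).
#'
#' @param t a `clinical_table` or numeric matrix.
#' @param train_index integer or logical index of training samples, or a
#'   character vector of sample ids.
#' @return `fit_standardizer` returns a `standardizer` (fields `center`,
#'   `scale`, `degenerate`); `apply_standardizer` returns an object of the
#'   same class as its input, transformed.
#' @export
fit_standardizer <- function(t, train_index = NULL) {
  v <- if (inherits(t, "clinical_table")) t$values else t
  if (is.null(train_index)) train_index <- seq_len(nrow(v))
  if (is.character(train_index)) train_index <- match(train_index, rownames(v))
  tr <- v[train_index, , drop = FALSE]
  if (nrow(tr) == 0) stop("fit_standardizer: empty train_index")
  center <- colMeans(tr, na.rm = TRUE)
  scale <- apply(tr, 2, sd, na.rm = TRUE)
  degenerate <- !is.finite(scale) | scale == 0
  center[degenerate] <- 0
  scale[degenerate] <- 1
  structure(list(center = center, scale = scale, degenerate = degenerate),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param s a fitted `standardizer`.
#' @export
apply_standardizer <- function(s, t) {
  stopifnot(inherits(s, "standardizer"))
  v <- if (inherits(t, "clinical_table")) t$values else t
  if (!identical(colnames(v), names(s$center)))
    v <- v[, names(s$center), drop = FALSE]
  v <- sweep(sweep(v, 2, s$center, `-`), 2, s$scale, `/`)
  if (inherits(t, "clinical_table")) { t$values <- v; t } else v
}

#' Stratification input columns of a clinical table
#'
#' Drops columns flagged `excluded` in the metadata (treatment and
#' doppler-derived measurements are never stratification inputs).
#'
#' @param t a `clinical_table`.
#' @return numeric matrix of the retained columns.
#' @export
stratification_inputs <- function(t) {
  stopifnot(inherits(t, "clinical_table"))
  t$values[, !t$meta$excluded, drop = FALSE]
}
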