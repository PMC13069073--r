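#' Log2-transform a raw protein matrix
#'
#' @param m `protein_matrix` in state `raw`; all present values must be
#'   strictly positive.
#' @return `protein_matrix` in state `log2`, same missingness pattern.
#' @export
log2_transform <- function(m) {
  assert_state(m, "raw", "log2_transform")
  v <- m$values
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("log2_transform: non-positive intensity at sample '%s', protein '%s'",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
  m$values <- log2(v)
  m$state <- "log2"
  m
}

#' Filter proteins by valid-value fraction
#'
#' Retains exactly the proteins quantified (non-missing) in at least
#' `min_fraction` of ALL samples — the inclusive "at least 70% of the total
#' samples analyzed" rule, computed across groups, not per group.
#'
#' @param m `protein_matrix`, any state.
#' @param min_fraction minimum non-missing fraction, in (0, 1]. Default 0.70.
#' @return the filtered `protein_matrix`, with a `filter_report` attribute
#'   (list: `n_retained`, `n_dropped`, `dropped` ids).
#' @export
filter_valid_fraction <- function(m, min_fraction = 0.70) {
  stopifnot(inherits(m, "protein_matrix"))
  if (!(min_fraction > 0 && min_fraction <= 1))
    stop("min_fraction must lie in (0, 1]")
  v <- m$values
  if (nrow(v) == 0 || ncol(v) == 0) stop("filter_valid_fraction: empty matrix")
  frac <- colMeans(!is.na(v))
  keep <- frac >= min_fraction
  m$values <- v[, keep, drop = FALSE]
  attr(m, "filter_report") <- list(n_retained = sum(keep),
                                   n_dropped = sum(!keep),
                                   dropped = colnames(v)[!keep],
                                   min_fraction = min_fraction)
  m
}

#' Impute missing log2 intensities from a downshifted normal
#'
#' Per sample, missing entries are drawn from
#' Normal(sample mean - `shift_sd` * sample SD, (`width_sd` * sample SD)^2),
#' the standard width-and-downshift convention for left-censored LFQ data
#' (defaults 1.8 / 0.3). Present values are untouched.
#'
#' @param m `protein_matrix` in state `log2`; every sample needs >= 2
#'   present values (its SD must be defined).
#' @param shift_sd downshift of the imputation distribution, in sample SDs.
#' @param width_sd width of the imputation distribution, in sample SDs.
#' @param seed RNG seed.
#' @return `protein_matrix` in state `imputed`, complete.
#' @export
impute_downshifted_normal <- function(m, shift_sd = 1.8, width_sd = 0.3,
                                      seed = 1L) {
  assert_state(m, "log2", "impute_downshifted_normal")
  v <- m$values
  npresent <- rowSums(!is.na(v))
  if (any(npresent < 2))
    stop("impute_downshifted_normal: sample(s) with < 2 present values (SD undefined): ",
         paste(rownames(v)[npresent < 2], collapse = ", "))
  with_seed(seed, {
    for (i in seq_len(nrow(v))) {
      miss <- is.na(v[i, ])
      if (!any(miss)) next
      mu <- mean(v[i, !miss])
      s <- sd(v[i, !miss])
      v[i, miss] <- rnorm(sum(miss), mean = mu - shift_sd * s,
                          sd = width_sd * s)
    }
    m$values <- v
    m$state <- "imputed"
    m
  })
}

# Core quantile normalization on a samples x features matrix: every row is
# forced onto the reference distribution of averaged order statistics; ties
# within a row receive the mean of the reference values their span covers.
quantile_normalize_matrix <- function(v) {
  n <- nrow(v)
  srt <- apply(v, 1, sort)            # features x samples
  ref <- rowMeans(srt)                # averaged order statistics
  out <- v
  for (i in seq_len(n)) {
    r <- rank(v[i, ], ties.method = "first")
    vals <- ref[r]
    # average reference values across tied spans
    out[i, ] <- stats::ave(vals, v[i, ], FUN = mean)
  }
  out
}

#' Quantile-normalize an imputed protein matrix
#'
#' Forces every sample's empirical distribution onto the reference formed by
#' averaging order statistics across samples. Requires a complete matrix:
#' per the processing order, imputation comes first.
#'
#' @param m `protein_matrix` in state `imputed`, no missing values.
#' @return `protein_matrix` in state `normalized`.
#' @export
quantile_normalize <- function(m) {
  assert_state(m, c("imputed", "normalized"), "quantile_normalize")
  if (anyNA(m$values))
    stop("quantile_normalize: missing values present; impute first")
  m$values <- quantile_normalize_matrix(m$values)
  m$state <- "normalized"
  m
}

# Vectorized two-sample pooled-variance t statistics for every column of v,
# comparing rows in ia vs ib. Returns list(t, diff, se_zero_flag).
pooled_t_stats <- function(v, ia, ib) {
  na <- length(ia); nb <- length(ib)
  ma <- colMeans(v[ia, , drop = FALSE])
  mb <- colMeans(v[ib, , drop = FALSE])
  va <- apply(v[ia, , drop = FALSE], 2, var)
  vb <- apply(v[ib, , drop = FALSE], 2, var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  degenerate <- se < .Machine$double.eps^0.5
  t <- (ma - mb) / se
  t[degenerate] <- NA_real_
  list(t = t, diff = ma - mb, degenerate = degenerate)
}

#' Permutation-FDR two-sample t-test
#'
#' Per protein, a two-sided pooled-variance two-sample t statistic comparing
#' two groups; significance is assessed against a permutation null built by
#' shuffling group labels (`n_permutations` shuffles, the same shuffles
#' reused across proteins). For a threshold t*, FDR(t*) is the mean
#' permutation count of |t_null| >= t* divided by the observed count of
#' |t| >= t*; each protein's q-value is the smallest FDR at which it is
#' called (monotone non-increasing in |t|), clipped to [0, 1]. Proteins with
#' zero pooled within-group variance get t = NA, q = 1 and a degenerate
#' flag — never significant.
#'
#' @param m `protein_matrix` in state `normalized`.
#' @param labels data.frame with `sample_id` and `group` covering the
#'   matrix samples, or a vector of group labels in matrix row order.
#' @param comparison length-2 character, e.g. `c("AT", "CTRL")` — the mean
#'   difference reported is first minus second.
#' @param n_permutations number of label shuffles (default 250).
#' @param alpha significance level on the q-value (default 0.05).
#' @param seed RNG seed for the shuffles.
#' @return a `differential_result` data.frame: `protein`, `comparison`,
#'   `log2_diff`, `t`, `q`, `significant`, `degenerate`; `alpha` and the
#'   permutation count as attributes.
#' @export
permutation_fdr_ttest <- function(m, labels, comparison,
                                  n_permutations = 250L, alpha = 0.05,
                                  seed = 1L) {
  assert_state(m, "normalized", "permutation_fdr_ttest")
  v <- m$values
  grp <- resolve_groups(labels, rownames(v), nrow(v))
  stopifnot(length(comparison) == 2)
  ia <- which(grp == comparison[1])
  ib <- which(grp == comparison[2])
  if (length(ia) < 3 || length(ib) < 3)
    stop("permutation_fdr_ttest: both groups need >= 3 samples")
  sub <- v[c(ia, ib), , drop = FALSE]
  n1 <- length(ia)
  ntot <- nrow(sub)
  obs <- pooled_t_stats(sub, seq_len(n1), (n1 + 1):ntot)
  abs_t <- abs(obs$t)

  null_abs <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      idx <- sample.int(ntot)
      abs(pooled_t_stats(sub, idx[seq_len(n1)], idx[(n1 + 1):ntot])$t)
    }, numeric(ncol(sub)))
  })
  null_vec <- sort(null_abs[!is.na(null_abs)])
  obs_sorted <- sort(abs_t[!is.na(abs_t)])

  q <- rep(1, ncol(sub))
  ok <- which(!is.na(abs_t))
  if (length(ok) > 0) {
    # counts of |t| >= threshold via sorted vectors
    n_null <- length(null_vec)
    n_obs <- length(obs_sorted)
    thr <- abs_t[ok]
    null_ge <- n_null - findInterval(thr - 1e-12, null_vec)
    obs_ge <- n_obs - findInterval(thr - 1e-12, obs_sorted)
    fdr <- (null_ge / n_permutations) / pmax(obs_ge, 1)
    fdr <- pmin(pmax(fdr, 0), 1)
    # q = min FDR over thresholds <= own |t|  (monotone in |t|)
    ord <- order(thr)
    fdr_sorted <- fdr[ord]
    # a protein is called at threshold t* iff |t| >= t*, so its q-value is
    # the running minimum of FDR over thresholds up to its own |t|
    qs <- cummin(fdr_sorted)
    q[ok[ord]] <- qs
  }
  res <- data.frame(protein = colnames(sub),
                    comparison = paste(comparison, collapse = " vs "),
                    log2_diff = unname(obs$diff),
                    t = unname(obs$t),
                    q = unname(q),
                    significant = unname(q < alpha & !obs$degenerate),
                    degenerate = unname(obs$degenerate),
                    stringsAsFactors = FALSE)
  if (any(obs$degenerate)) {
    res$q[res$degenerate] <- 1
    res$significant[res$degenerate] <- FALSE
    warning(sum(obs$degenerate), " protein(s) with zero within-group variance: q set to 1")
  }
  attr(res, "alpha") <- alpha
  attr(res, "n_permutations") <- n_permutations
  class(res) <- c("differential_result", class(res))
  res
}

# Map a labels data.frame (sample_id, group) or plain vector onto the given
# sample order; `n` guards plain vectors when row names are absent.
resolve_groups <- function(labels, sample_ids, n = length(sample_ids)) {
  if (is.data.frame(labels)) {
    if (is.null(sample_ids))
      stop("matrix must carry sample ids to join against a labels table")
    idx <- match(sample_ids, labels$sample_id)
    if (anyNA(idx))
      stop("labels missing for sample(s): ",
           paste(sample_ids[is.na(idx)], collapse = ", "))
    labels$group[idx]
  } else {
    if (length(labels) != n)
      stop("label vector length does not match samples")
    as.character(labels)
  }
}

#' Run the full proteomic post-processing chain
#'
#' Convenience composition in the fixed order: log2 transform, valid-value
#' filter, downshifted-normal imputation, quantile normalization.
#'
#' @inheritParams filter_valid_fraction
#' @inheritParams impute_downshifted_normal
#' @return `protein_matrix` in state `normalized`.
#' @export
prep_protein_matrix <- function(m, min_fraction = 0.70, shift_sd = 1.8,
                                width_sd = 0.3, seed = 1L) {
  m <- log2_transform(m)
  m <- filter_valid_fraction(m, min_fraction)
  report <- attr(m, "filter_report")
  m <- impute_downshifted_normal(m, shift_sd, width_sd, seed = seed)
  m <- quantile_normalize(m)
  attr(m, "filter_report") <- report
  m
}

#' Write a differential-testing result as CSV
#' @param res a `differential_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_differential_csv <- function(res, path) {
  utils::write.csv(res[, c("protein", "comparison", "log2_diff", "t", "q",
                           "significant")], path, row.names = FALSE)
  invisible(path)
}
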