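test_that("log2_transform matches an elementwise oracle and flags bad cells", {
  m <- toy_protein_matrix(matrix(c(8, 1, 2, 4, NA, 16), 3, 2))
  lg <- log2_transform(m)
  expect_identical(lg$state, "log2")
  expect_equal(lg$values[1, 1], 3)
  expect_equal(lg$values[2, 1], 0)
  expect_true(is.na(lg$values[2, 2]))
  set.seed(9)
  v <- matrix(2^rnorm(6, 10), 3, 2)
  m2 <- toy_protein_matrix(v)
  expect_equal(log2_transform(m2)$values, log(v, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("filter_valid_fraction uses an inclusive boundary over all samples", {
  v <- matrix(1, 10, 2)
  v[1:3, 1] <- NA  # 7/10 valid -> retained at 0.70
  v[1:4, 2] <- NA  # 6/10 valid -> dropped
  m <- toy_protein_matrix(v)
  f <- filter_valid_fraction(m, 0.70)
  expect_identical(colnames(f$values), "p01")
  rep <- attr(f, "filter_report")
  expect_equal(rep$n_retained, 1L)
  expect_identical(rep$dropped, "p02")

  # brute-force counting oracle on a random grid + monotonicity
  set.seed(4)
  v <- matrix(runif(200, 1, 10), 10, 20,
              dimnames = list(sprintf("s%02d", 1:10), sprintf("p%02d", 1:20)))
  v[sample(200, 70)] <- NA
  m <- toy_protein_matrix(v)
  prev <- colnames(v)
  for (th in c(0.3, 0.5, 0.7, 0.9)) {
    keep_oracle <- colnames(v)[vapply(seq_len(20), function(j)
      sum(!is.na(v[, j])) >= th * 10, logical(1))]
    got <- colnames(filter_valid_fraction(m, th)$values)
    expect_identical(got, keep_oracle)
    expect_true(all(got %in% prev))  # raising threshold never adds proteins
    prev <- got
  }
})

test_that("downshifted-normal imputation draws from the stated distribution", {
  # single sample with known mean/SD on the log2 scale, many missing slots
  present <- c(18, 20, 22, 20, 18, 22, 20, 20)
  n_miss <- 10000
  v <- matrix(c(present, rep(NA, n_miss)), 1, length(present) + n_miss)
  m <- log2_transform(toy_protein_matrix(2^v, state = "raw"))
  imp <- impute_downshifted_normal(m, shift_sd = 1.8, width_sd = 0.3, seed = 7)
  mu <- mean(present); s <- sd(present)
  draws <- imp$values[1, -(seq_along(present))]
  se_mean <- (0.3 * s) / sqrt(n_miss)
  expect_lt(abs(mean(draws) - (mu - 1.8 * s)), 3 * se_mean)
  expect_lt(abs(sd(draws) - 0.3 * s), 3 * (0.3 * s) / sqrt(2 * n_miss))
  # reproducibility and identity on complete data
  imp2 <- impute_downshifted_normal(m, seed = 7)
  expect_identical(imp$values, imp2$values)
  complete <- toy_protein_matrix(matrix(rnorm(12, 20), 3, 4), state = "log2")
  expect_equal(impute_downshifted_normal(complete, seed = 1)$values,
               complete$values)
  # SD undefined
  bad <- toy_protein_matrix(matrix(c(20, NA, NA, NA), 1, 4), state = "log2")
  expect_error(impute_downshifted_normal(bad), "< 2 present")
})

test_that("quantile normalization equals the sort-average-reassign oracle", {
  m <- toy_protein_matrix(rbind(c(1, 2, 3), c(4, 5, 6)), state = "imputed")
  qn <- quantile_normalize(m)
  expect_equal(unname(qn$values[1, ]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[2, ]), c(2.5, 3.5, 4.5))

  same <- toy_protein_matrix(rbind(c(1, 5, 9), c(1, 5, 9)), state = "imputed")
  expect_equal(quantile_normalize(same)$values, same$values)

  set.seed(8)
  v <- matrix(rnorm(30, 20), 6, 5)
  qn <- quantile_normalize(toy_protein_matrix(v, state = "imputed"))
  ref <- rowMeans(apply(v, 1, sort))
  oracle <- t(apply(v, 1, function(row) {
    out <- numeric(length(row))
    r <- rank(row, ties.method = "first")
    out <- ref[r]
    ave(out, row, FUN = mean)
  }))
  expect_equal(qn$values, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # every sample shares the same sorted values
  for (i in 2:6)
    expect_equal(unname(sort(qn$values[i, ])), unname(sort(qn$values[1, ])),
                 tolerance = 1e-12)
  # idempotence
  qn2 <- quantile_normalize(qn)
  expect_equal(qn2$values, qn$values, tolerance = 1e-10)
  # ties take the mean of the reference span
  vt <- rbind(c(1, 1, 5), c(2, 4, 9), c(3, 6, 7))
  qt <- quantile_normalize(toy_protein_matrix(vt, state = "imputed"))
  reft <- rowMeans(apply(vt, 1, sort))
  expect_equal(unname(qt$values[1, 1:2]), rep(mean(reft[1:2]), 2))
  # refuses missing values
  vm <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(quantile_normalize(toy_protein_matrix(vm, state = "imputed")),
               "impute first")
})

test_that("permutation-FDR t-test calls strong effects and handles degeneracy", {
  set.seed(15)
  n <- 40
  v <- matrix(rnorm(n * 30, 20), n, 30)
  v[1:20, 1] <- v[1:20, 1] + 3   # 3 SD shift, n = 20 vs 20
  v[, 2] <- 20                    # zero variance everywhere
  m <- toy_protein_matrix(v, state = "imputed")
  m <- quantile_normalize(m)
  m$values[, 2] <- 20             # keep the degenerate column degenerate
  labels <- rep(c("AT", "CTRL"), each = 20)
  expect_warning(
    res <- permutation_fdr_ttest(m, labels, c("AT", "CTRL"),
                                 n_permutations = 200, seed = 31),
    "zero within-group variance")
  # reference oracle: plain two-sample t-test is overwhelming for protein 1
  pt <- t.test(m$values[1:20, 1], m$values[21:40, 1], var.equal = TRUE)$p.value
  expect_lt(pt, 1e-6)
  expect_true(res$significant[1])
  expect_lt(res$q[1], 0.05)
  expect_true(res$degenerate[2])
  expect_equal(res$q[2], 1)
  expect_false(res$significant[2])
  # q-values are non-increasing in |t|
  ok <- !is.na(res$t)
  ord <- order(abs(res$t[ok]), decreasing = TRUE)
  expect_true(all(diff(res$q[ok][ord]) >= -1e-12))
  # mean difference sign and magnitude
  expect_gt(res$log2_diff[1], 2)
})

test_that("the composed prep chain flags injected markers end to end", {
  b <- generate_cohort(preset_config("paper_discovery"))
  prot <- prep_protein_matrix(b$proteins, seed = 5)
  expect_identical(prot$state, "normalized")
  expect_false(anyNA(prot$values))
  res <- permutation_fdr_ttest(prot, b$labels, c("AT", "CTRL"),
                               n_permutations = 200, seed = 6)
  markers <- grep("^marker_", res$protein)
  expect_true(all(res$significant[markers]))
})
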