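test_that("reassignment fires iff >= 3 of 5 models flag, over all patterns", {
  # exhaustive 2^5 flag patterns, probabilities 0.9 (flag) / 0.1 (no flag)
  for (bits in 0:31) {
    flags <- as.integer(intToBits(bits))[1:5] == 1
    prob <- matrix(ifelse(flags, 0.9, 0.1), 1, 5)
    mm <- manual_misclass(prob, y_pre = "CTRL")
    res <- consensus_reassign(mm)
    expect_identical(res$reassigned, sum(flags) >= 3)
    if (sum(flags) >= 3) expect_identical(res$post_label, "DLP")
    else expect_identical(res$post_label, "CTRL")
  }
})

test_that("boundary probabilities behave as printed: strictly exceeding 50%", {
  mm <- manual_misclass(matrix(c(0.6, 0.7, 0.8, 0.1, 0.2), 1, 5), "CTRL")
  expect_true(consensus_reassign(mm)$reassigned)
  # exactly 0.5 in three models does NOT flag
  mm2 <- manual_misclass(matrix(c(0.5, 0.5, 0.5, 0.9, 0.1), 1, 5), "CTRL")
  expect_false(consensus_reassign(mm2)$reassigned)
  # all zero: identity relabeling, rate 0
  mm3 <- manual_misclass(matrix(0, 4, 5), rep(c("CTRL", "AT"), 2))
  res3 <- consensus_reassign(mm3)
  expect_false(any(res3$reassigned))
  expect_identical(res3$post_label, res3$pre_label)
  expect_equal(misclassification_rate(res3), 0)
  expect_error(consensus_reassign(mm3, min_models = 6), "exceeds")
})

test_that("post-label voting uses majority, then frequency, then group order", {
  prob <- matrix(c(0.9, 0.9, 0.9, 0.9, 0.1), 1, 5)
  modal <- matrix(c("DLP", "DLP", "AT", "AT", NA), 1, 5)
  # frequency tie-break: AT predicted more often by its voters
  altf <- matrix(c(0.6, 0.6, 0.9, 0.9, 0), 1, 5)
  mm <- manual_misclass(prob, "CTRL", modal_alt = modal, alt_freq = altf)
  expect_identical(consensus_reassign(mm)$post_label, "AT")
  # full tie: fixed order CTRL < DLP < AT decides
  altf2 <- matrix(c(0.6, 0.6, 0.6, 0.6, 0), 1, 5)
  mm2 <- manual_misclass(prob, "CTRL", modal_alt = modal, alt_freq = altf2)
  expect_identical(consensus_reassign(mm2)$post_label, "DLP")
  # clear majority ignores frequencies
  modal3 <- matrix(c("AT", "AT", "AT", "DLP", NA), 1, 5)
  mm3 <- manual_misclass(prob, "CTRL", modal_alt = modal3, alt_freq = altf)
  expect_identical(consensus_reassign(mm3)$post_label, "AT")
})

test_that("reassignments are doubly monotone in threshold and min_models", {
  set.seed(79)
  for (rep_i in 1:10) {
    prob <- matrix(runif(20 * 5), 20, 5)
    mm <- manual_misclass(prob, rep(c("CTRL", "DLP"), 10))
    n_prev <- Inf
    for (th in c(0.3, 0.5, 0.7)) {
      n_now <- sum(consensus_reassign(mm, threshold = th)$reassigned)
      expect_lte(n_now, n_prev)
      n_prev <- n_now
    }
    n_prev <- Inf
    for (k in 1:5) {
      n_now <- sum(consensus_reassign(mm, min_models = k)$reassigned)
      expect_lte(n_now, n_prev)
      n_prev <- n_now
    }
  }
})

test_that("consensus robustness holds where the 3-of-5 rule guarantees it", {
  # (a) perturbations that flip no flag never change any decision
  set.seed(83)
  prob <- matrix(runif(10 * 5), 10, 5)
  mm <- manual_misclass(prob, rep("CTRL", 10))
  base <- consensus_reassign(mm)$reassigned
  for (i in 1:20) {
    pert <- prob
    cols <- sample(5, 2)
    # move 2 models' probabilities arbitrarily within their flag side
    for (cc in cols)
      pert[, cc] <- ifelse(prob[, cc] > 0.5, runif(10, 0.5001, 1),
                           runif(10, 0, 0.5))
    mmp <- manual_misclass(pert, rep("CTRL", 10))
    expect_identical(consensus_reassign(mmp)$reassigned, base)
  }
  # (b) unanimous patterns tolerate arbitrary perturbation of any 2 models
  for (cols in utils::combn(5, 2, simplify = FALSE)) {
    p5 <- matrix(0.9, 1, 5); p5[1, cols] <- 0   # 5 flags -> still >= 3
    expect_true(consensus_reassign(manual_misclass(p5, "CTRL"))$reassigned)
    p0 <- matrix(0.1, 1, 5); p0[1, cols] <- 1   # 0 flags -> still <= 2
    expect_false(consensus_reassign(manual_misclass(p0, "CTRL"))$reassigned)
  }
})

test_that("misclassification probabilities behave at the extremes", {
  tc <- toy_classes(n_per = 15, sep = 6, seed = 13)
  models <- small_models()
  mm <- misclassification_probability(tc$X, tc$y, models = models,
                                      scheme = cv_scheme(2, 3, seed = 3))
  expect_true(all(mm$prob >= 0 & mm$prob <= 1))
  expect_lt(mean(mm$prob[, c("RF", "ETC")]), 0.05)  # separable data
  # determinism
  mm2 <- misclassification_probability(tc$X, tc$y, models = models,
                                       scheme = cv_scheme(2, 3, seed = 3))
  expect_identical(mm$prob, mm2$prob)
  # permuted labels on noise: mean probability near chance (2/3)
  set.seed(17)
  Xn <- matrix(rnorm(150 * 5), 150, 5,
               dimnames = list(sprintf("s%03d", 1:150), sprintf("f%d", 1:5)))
  yn <- rep(c("CTRL", "DLP", "AT"), each = 50)
  mmn <- misclassification_probability(Xn, yn, models = models["NB"],
                                       scheme = cv_scheme(3, 3, seed = 5))
  expect_lt(abs(mean(mmn$prob) - 2 / 3), 0.12)
})

test_that("compare_modalities reports rates and rejects misaligned inputs", {
  prob_hi <- matrix(0.9, 60, 5); prob_lo <- matrix(0, 60, 5)
  prob_lo[1:3, ] <- 0.9   # 3 reassigned of 60 -> 5%
  ids <- sprintf("i%02d", 1:60)
  rownames(prob_hi) <- rownames(prob_lo) <- ids
  y <- rep(c("CTRL", "DLP", "AT"), 20)
  r1 <- consensus_reassign(manual_misclass(prob_lo, y, modality = "combined"))
  r2 <- consensus_reassign(manual_misclass(prob_hi, y, modality = "clinical"))
  expect_equal(misclassification_rate(r1), 5)
  cmp <- compare_modalities(list(combined = r1, clinical = r2))
  expect_equal(cmp$rates$rate[cmp$rates$modality == "combined"], 5)
  expect_equal(cmp$rates$n_reassigned[cmp$rates$modality == "clinical"], 60)
  expect_identical(dim(cmp$agreement), c(60L, 2L))
  r3 <- r1[1:59, ]
  expect_error(compare_modalities(list(a = r1, b = r3)), "different individual")
})
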