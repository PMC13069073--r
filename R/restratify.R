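#' Per-individual misclassification probabilities
#'
#' Runs the five-model bank through a repeated stratified CV scheme and,
#' for each model, defines an individual's misclassification probability as
#' the fraction of its out-of-fold predictions (one per CV repetition)
#' that disagree with the pre-assigned label: 0 means every held-out
#' prediction matched the pre-label, 1 means the model always placed the
#' individual elsewhere. The modal alternative class among the
#' misclassified predictions, and the frequency with which it was
#' predicted, are recorded for the reassignment vote.
#'
#' @param X samples x features matrix (treatment/doppler-flagged columns
#'   must already be excluded; see [stratification_inputs()]).
#' @param y_pre pre-assigned group labels.
#' @param models classifier bank.
#' @param scheme a [cv_scheme()].
#' @param modality label stamped on the result (`"clinical"`,
#'   `"proteomic"`, `"combined"`, ...).
#' @param seed optional seed override.
#' @return a `misclass_matrix`: list with `prob` (individuals x models),
#'   `modal_alt` (character, NA where never misclassified), `alt_freq`
#'   (fraction of repeats predicting the modal alternative), `y_pre`,
#'   `modality`, `sample_ids`.
#' @export
misclassification_probability <- function(X, y_pre,
                                          models = build_classifiers(),
                                          scheme = cv_scheme(20, 3),
                                          modality = "combined",
                                          seed = NULL) {
  X <- as.matrix(X)
  y_pre <- as.character(y_pre)
  cp <- cv_predictions(X, y_pre, models, scheme, seed)
  n <- nrow(X)
  nm <- length(models)
  prob <- matrix(0, n, nm, dimnames = list(rownames(X), names(models)))
  modal <- matrix(NA_character_, n, nm, dimnames = dimnames(prob))
  altf <- matrix(0, n, nm, dimnames = dimnames(prob))
  for (mi in seq_len(nm)) {
    preds <- vapply(cp$repeats, function(rp) rp$pred[[mi]], character(n))
    if (n == 1) preds <- matrix(preds, nrow = 1)
    mis <- preds != matrix(y_pre, n, scheme$n_repeats)
    prob[, mi] <- rowMeans(mis)
    for (i in seq_len(n)) {
      wrong <- preds[i, mis[i, ]]
      if (length(wrong) > 0) {
        tab <- sort(table(wrong), decreasing = TRUE)
        top <- names(tab)[tab == max(tab)]
        # deterministic modal pick: fixed group order breaks count ties
        top <- top[order(match(top, group_levels()), top)][1]
        modal[i, mi] <- top
        altf[i, mi] <- sum(preds[i, ] == top) / scheme$n_repeats
      }
    }
  }
  structure(list(prob = prob, modal_alt = modal, alt_freq = altf,
                 y_pre = setNames(y_pre, rownames(X)), modality = modality,
                 sample_ids = rownames(X)),
            class = "misclass_matrix")
}

#' @export
print.misclass_matrix <- function(x, ...) {
  cat(sprintf("<misclass_matrix> modality '%s': %d individuals x %d models, mean prob %.3f\n",
              x$modality, nrow(x$prob), ncol(x$prob), mean(x$prob)))
  invisible(x)
}

#' Consensus re-stratification
#'
#' An individual is flagged by a model when its misclassification
#' probability strictly exceeds `threshold` (50% by default), and
#' reassigned when at least `min_models` of the bank flag it (3 of 5 by
#' default). The post-label is the majority modal alternative class among
#' the flagging models; ties are broken toward the class with the highest
#' mean predicted-alternative frequency, then by the fixed group order
#' CTRL < DLP < AT. Unreassigned individuals keep their pre-label.
#'
#' @param m a `misclass_matrix`.
#' @param threshold strict flagging threshold on the probability.
#' @param min_models minimum number of flagging models.
#' @return a `stratification_result`: data.frame (`sample_id`, `pre_label`,
#'   `n_flagging`, `post_label`, `reassigned`) with attributes `rate`
#'   (percent reassigned) and `modality`.
#' @export
consensus_reassign <- function(m, threshold = 0.5, min_models = 3L) {
  stopifnot(inherits(m, "misclass_matrix"))
  if (anyNA(m$prob)) stop("misclassification matrix is incomplete")
  nm <- ncol(m$prob)
  if (min_models > nm)
    stop("min_models exceeds the number of models (", nm, ")")
  flags <- m$prob > threshold
  n_flag <- rowSums(flags)
  reassigned <- n_flag >= min_models
  post <- m$y_pre
  for (i in which(reassigned)) {
    voters <- which(flags[i, ])
    alts <- m$modal_alt[i, voters]
    freqs <- m$alt_freq[i, voters]
    ok <- !is.na(alts)
    alts <- alts[ok]; freqs <- freqs[ok]
    if (length(alts) == 0) {  # flagged but no recorded alternative: keep
      reassigned[i] <- FALSE
      next
    }
    votes <- tapply(rep(1, length(alts)), alts, sum)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      mean_freq <- vapply(top, function(cls) mean(freqs[alts == cls]),
                          numeric(1))
      top <- top[mean_freq == max(mean_freq)]
      if (length(top) > 1)
        top <- top[order(match(top, group_levels()), top)]
    }
    post[i] <- top[1]
  }
  out <- data.frame(sample_id = m$sample_ids,
                    pre_label = unname(m$y_pre),
                    n_flagging = unname(n_flag),
                    post_label = unname(post),
                    reassigned = unname(reassigned),
                    stringsAsFactors = FALSE)
  attr(out, "rate") <- 100 * mean(reassigned)
  attr(out, "modality") <- m$modality
  class(out) <- c("stratification_result", class(out))
  out
}

#' Misclassification rate of a stratification result (percent)
#' @param res a `stratification_result`.
#' @return numeric percentage of reassigned individuals.
#' @export
misclassification_rate <- function(res) attr(res, "rate")

#' Compare stratification across data modalities
#'
#' @param results named list of `stratification_result` objects (e.g.
#'   clinical / proteomic / combined), all over the same individuals.
#' @return list with `rates` (data.frame modality, rate, n_reassigned,
#'   concordance_pct), `agreement` (individuals x modalities reassignment
#'   grid) and `per_individual` (long table of reassignments).
#' @export
compare_modalities <- function(results) {
  stopifnot(length(results) >= 1)
  ids <- results[[1]]$sample_id
  for (r in results)
    if (!identical(sort(r$sample_id), sort(ids)))
      stop("modalities cover different individual sets")
  rates <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(modality = nm,
               rate = attr(r, "rate"),
               n_reassigned = sum(r$reassigned),
               n_total = nrow(r),
               concordance_pct = 100 * mean(r$post_label == r$pre_label),
               stringsAsFactors = FALSE)
  }))
  agreement <- vapply(results, function(r)
    r$reassigned[match(ids, r$sample_id)], logical(length(ids)))
  rownames(agreement) <- ids
  long <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    r <- r[r$reassigned, , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    data.frame(modality = nm, r, stringsAsFactors = FALSE)
  }))
  list(rates = rates, agreement = agreement, per_individual = long)
}

#' Long-format per-individual stratification table
#'
#' One row per (individual, model): misclassification probability, flag
#' state and pre/post labels — the per-column layout used to visualize
#' consensus re-stratification.
#'
#' @param m a `misclass_matrix`.
#' @param res the matching `stratification_result`.
#' @param threshold the flagging threshold used.
#' @return data.frame `sample_id`, `modality`, `model`, `probability`,
#'   `flagged`, `pre_label`, `post_label`.
#' @export
stratification_long_table <- function(m, res, threshold = 0.5) {
  stopifnot(inherits(m, "misclass_matrix"))
  idx <- match(m$sample_ids, res$sample_id)
  do.call(rbind, lapply(colnames(m$prob), function(mod) {
    data.frame(sample_id = m$sample_ids, modality = m$modality, model = mod,
               probability = unname(m$prob[, mod]),
               flagged = unname(m$prob[, mod] > threshold),
               pre_label = res$pre_label[idx],
               post_label = res$post_label[idx],
               stringsAsFactors = FALSE)
  }))
}
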