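#' Repeated stratified cross-validation scheme
#'
#' @param n_repeats number of CV repetitions (>= 1).
#' @param n_folds folds per repetition (>= 2).
#' @param stratified keep class proportions balanced across folds.
#' @param seed RNG seed for fold assignment.
#' @return a `cv_scheme` object.
#' @export
cv_scheme <- function(n_repeats = 3L, n_folds = 5L, stratified = TRUE,
                      seed = 1L) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (n_folds < 2) stop("n_folds must be >= 2")
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Fold assignments for a label vector
#'
#' Returns one integer fold-id vector (values `1..n_folds`) per repetition.
#' Stratified assignment deals each class's shuffled samples round-robin
#' into folds, so every fold holds every class; it errors when a class has
#' fewer samples than folds.
#'
#' @param y class labels.
#' @param scheme a [cv_scheme()].
#' @param seed optional seed override.
#' @return list of length `n_repeats` of integer vectors.
#' @export
make_folds <- function(y, scheme, seed = NULL) {
  stopifnot(inherits(scheme, "cv_scheme"))
  y <- as.character(y)
  n <- length(y)
  if (scheme$stratified) {
    tab <- table(y)
    if (any(tab < scheme$n_folds))
      stop("stratification error: class(es) with fewer samples than folds: ",
           paste(names(tab)[tab < scheme$n_folds], collapse = ", "))
  }
  seed <- if (is.null(seed)) scheme$seed else seed
  with_seed(seed, {
    lapply(seq_len(scheme$n_repeats), function(r) {
      fold <- integer(n)
      if (scheme$stratified) {
        for (cls in unique(y)) {
          idx <- sample(which(y == cls))
          fold[idx] <- rep_len(seq_len(scheme$n_folds), length(idx))
        }
      } else {
        fold <- sample(rep_len(seq_len(scheme$n_folds), n))
      }
      fold
    })
  })
}
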