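# Shared fixture builders: everything is generated in code, no stored data.

toy_protein_matrix <- function(values, state = "raw") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("p%02d", seq_len(ncol(values)))
  protein_matrix(values, state = state)
}

toy_clinical <- function(values, ...) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("f%02d", seq_len(ncol(values)))
  clinical_table(values, ...)
}

# A small, well-separated 3-class dataset; `sep` controls class distance.
toy_classes <- function(n_per = 20, p = 6, sep = 4, seed = 42) {
  set.seed(seed)
  y <- rep(c("CTRL", "DLP", "AT"), each = n_per)
  X <- matrix(rnorm(3 * n_per * p), 3 * n_per, p,
              dimnames = list(sprintf("s%03d", seq_len(3 * n_per)),
                              sprintf("f%02d", seq_len(p))))
  X[y == "DLP", 1] <- X[y == "DLP", 1] + sep
  X[y == "AT", 2] <- X[y == "AT", 2] + sep
  list(X = X, y = y)
}

# Small classifier bank for runtime-sensitive tests; hyperparameters are a
# documented runtime scale-down, never a threshold change.
small_models <- function() {
  build_classifiers(list(RF = list(n_trees = 30L), ETC = list(n_trees = 30L),
                         AB = list(n_stumps = 25L)))
}

# Hand-rolled misclass_matrix for rule-logic tests.
manual_misclass <- function(prob, y_pre, modal_alt = NULL, alt_freq = NULL,
                            modality = "combined") {
  n <- nrow(prob)
  if (is.null(rownames(prob))) rownames(prob) <- sprintf("i%02d", seq_len(n))
  if (is.null(colnames(prob))) colnames(prob) <- model_names()[seq_len(ncol(prob))]
  if (is.null(modal_alt)) {
    modal_alt <- matrix("DLP", n, ncol(prob), dimnames = dimnames(prob))
    modal_alt[prob == 0] <- NA_character_
  }
  if (is.null(alt_freq)) alt_freq <- prob
  structure(list(prob = prob, modal_alt = modal_alt, alt_freq = alt_freq,
                 y_pre = stats::setNames(y_pre, rownames(prob)),
                 modality = modality, sample_ids = rownames(prob)),
            class = "misclass_matrix")
}

# Full-pipeline configuration with every stage scaled down for runtime
# (schemes, permutation counts and ensemble sizes shrink; decision
# thresholds keep their reference values).
small_pipeline_config <- function(seed = 101L) {
  run_config(preset = "paper_discovery", seed = seed,
             n_permutations_fdr = 60L,
             select_scheme = cv_scheme(1, 3, seed = seed),
             eval_scheme = cv_scheme(2, 3, seed = seed),
             n_bootstrap = 6L,
             model_config = list(RF = list(n_trees = 20L),
                                 ETC = list(n_trees = 20L),
                                 AB = list(n_stumps = 15L)))
}
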