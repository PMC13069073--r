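#' Protein intensity matrix
#'
#' A sample-by-protein grid of label-free quantification (LFQ) intensities
#' with explicit missingness and a processing-state flag. The state records
#' where the matrix sits in the fixed post-processing chain
#' `raw -> log2 -> imputed -> normalized`; operations check it so stages
#' cannot be applied out of order (filtering is allowed at any state).
#'
#' @param values numeric matrix, samples in rows, proteins in columns;
#'   `NA` marks a missing (not quantified) intensity. Row and column names
#'   are the sample and protein identifiers.
#' @param state one of `"raw"`, `"log2"`, `"imputed"`, `"normalized"`.
#' @return an object of class `protein_matrix`.
#' @export
protein_matrix <- function(values, state = c("raw", "log2", "imputed", "normalized")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x proteins)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample ids (rownames) and protein ids (colnames)")
  if (anyDuplicated(rownames(values))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicated protein ids")
  if (state == "raw") {
    bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("raw intensities must be strictly positive; first offender: sample '%s', protein '%s'",
                   rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  } else {
    if (any(!is.finite(values) & !is.na(values)))
      stop("post-log2 values must be finite")
  }
  structure(list(values = values, state = state), class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("<protein_matrix> %d samples x %d proteins, state '%s', %.1f%% missing\n",
              nrow(v), ncol(v), x$state, 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

state_index <- c(raw = 1L, log2 = 2L, imputed = 3L, normalized = 4L)

assert_state <- function(m, expected, op) {
  if (!inherits(m, "protein_matrix")) stop(op, ": not a protein_matrix")
  if (!m$state %in% expected)
    stop(sprintf("%s: matrix state is '%s' but must be %s", op, m$state,
                 paste(sQuote(expected), collapse = " or ")))
  invisible(TRUE)
}

#' Clinical feature table
#'
#' Sample-by-feature table of clinical measurements (lipid panel, hemogram,
#' biochemistry, encoded binary risk factors). Categorical features must be
#' pre-encoded to 0/1 indicators; a metadata sheet flags feature type and
#' whether a column is excluded from stratification inputs (treatment and
#' doppler-derived measurements are, per the stratification protocol).
#'
#' @param values numeric matrix, samples x features, `NA` = missing.
#' @param meta data.frame with columns `feature`, `type` (`"numeric"` or
#'   `"binary"`) and `excluded` (logical); defaults to all-numeric,
#'   none excluded.
#' @return an object of class `clinical_table`.
#' @export
clinical_table <- function(values, meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x features)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample ids (rownames) and feature ids (colnames)")
  if (anyDuplicated(colnames(values))) stop("duplicated feature ids")
  if (is.null(meta)) {
    meta <- data.frame(feature = colnames(values), type = "numeric",
                       excluded = FALSE, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("feature", "type", "excluded") %in% names(meta)))
  if (!setequal(meta$feature, colnames(values)))
    stop("metadata features do not match table columns")
  meta <- meta[match(colnames(values), meta$feature), , drop = FALSE]
  rownames(meta) <- NULL
  for (j in which(meta$type == "binary")) {
    v <- values[, j]
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      stop(sprintf("binary feature '%s' contains values outside {0,1,NA}", meta$feature[j]))
  }
  structure(list(values = values, meta = meta), class = "clinical_table")
}

#' @export
print.clinical_table <- function(x, ...) {
  cat(sprintf("<clinical_table> %d samples x %d features (%d excluded from stratification), %.1f%% missing\n",
              nrow(x$values), ncol(x$values), sum(x$meta$excluded),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.clinical_table <- function(x) dim(x$values)

#' Read / write the protein matrix TSV dialect
#'
#' Tab-separated, first column `sample_id`, remaining columns protein
#' identifiers; an empty cell is a missing value.
#'
#' @param m a `protein_matrix`.
#' @param path file path.
#' @param state processing state to stamp on the matrix read back in.
#' @return `read_protein_tsv` returns a `protein_matrix`;
#'   `write_protein_tsv` returns `path` invisibly.
#' @export
write_protein_tsv <- function(m, path) {
  stopifnot(inherits(m, "protein_matrix"))
  df <- data.frame(sample_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_protein_tsv
#' @export
read_protein_tsv <- function(path, state = "raw") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          na.strings = "", stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- as.character(df[[1]])
  protein_matrix(v, state = state)
}

#' Read / write the clinical CSV dialect
#'
#' Comma-separated, first column `sample_id`; an optional metadata sidecar
#' (columns `feature`, `type`, `excluded`) marks feature types and columns
#' excluded from stratification.
#'
#' @param t a `clinical_table`.
#' @param path file path.
#' @param meta_path optional sidecar CSV path.
#' @return `read_clinical_csv` returns a `clinical_table`;
#'   `write_clinical_csv` returns `path` invisibly.
#' @export
write_clinical_csv <- function(t, path, meta_path = NULL) {
  stopifnot(inherits(t, "clinical_table"))
  df <- data.frame(sample_id = rownames(t$values), t$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(meta_path)) utils::write.csv(t$meta, meta_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_csv
#' @export
read_clinical_csv <- function(path, meta_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                        stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- as.character(df[[1]])
  meta <- if (!is.null(meta_path)) utils::read.csv(meta_path, stringsAsFactors = FALSE) else NULL
  clinical_table(v, meta = meta)
}

#' Read / write sample labels
#'
#' CSV with columns `sample_id`, `group` (one of CTRL, DLP, AT) and
#' `cohort` (`discovery` or `external`).
#'
#' @param labels data.frame with the three columns above.
#' @param path file path.
#' @return `read_labels_csv` returns the labels data.frame;
#'   `write_labels_csv` returns `path` invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  stopifnot(all(c("sample_id", "group", "cohort") %in% names(labels)))
  utils::write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "group", "cohort") %in% names(df)))
  df
}

#' Canonical group order used for tie-breaking
#' @return character vector `c("CTRL", "DLP", "AT")`.
#' @export
group_levels <- function() c("CTRL", "DLP", "AT")
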