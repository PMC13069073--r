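#' Pipeline run configuration
#'
#' Bundles every numeric constant of the workflow — the preprocessing
#' thresholds (0.70 valid fraction, 1.8/0.3 imputation), the selection
#' rules (0.60 bootstrap retention, 0.20 fold consensus, 0.85 dedup rho,
#' 0.25 RFE target), the panel filter (AUC > 0.7), the reassignment rule
#' (> 0.5 in >= 3 of 5 models) and the CV schemes — plus either a synthetic
#' preset name or paths to the three input files.
#'
#' @param preset synthetic preset name (see [preset_config()]), or `NULL`
#'   when `paths` is given.
#' @param paths named list (`proteins`, `clinical`, `clinical_meta`,
#'   `labels`) of input files; exactly one of `preset`/`paths`.
#' @param min_valid_fraction,impute_shift_sd,impute_width_sd proteomics
#'   preprocessing parameters.
#' @param n_permutations_fdr permutation count for differential testing.
#' @param select_scheme,eval_scheme CV schemes for selection (reference
#'   3x5) and evaluation (reference 20x3).
#' @param n_bootstrap,fold_threshold,retain_fraction,target_fraction,rho_threshold
#'   consensus-selection parameters.
#' @param auc_threshold dual-comparison panel filter threshold.
#' @param misclass_threshold,min_models consensus reassignment rule.
#' @param model_config hyperparameter overrides for [build_classifiers()].
#' @param seed root seed; every stage derives its own child seed from it.
#' @return a validated `run_config`.
#' @export
run_config <- function(preset = "paper_discovery", paths = NULL,
                       min_valid_fraction = 0.70,
                       impute_shift_sd = 1.8, impute_width_sd = 0.3,
                       n_permutations_fdr = 250L,
                       select_scheme = cv_scheme(3, 5),
                       eval_scheme = cv_scheme(20, 3),
                       n_bootstrap = 50L,
                       fold_threshold = 0.20,
                       retain_fraction = 0.60,
                       target_fraction = 0.25,
                       rho_threshold = 0.85,
                       auc_threshold = 0.7,
                       misclass_threshold = 0.5,
                       min_models = 3L,
                       model_config = list(),
                       seed = 20180101L) {
  if (is.null(preset) == is.null(paths))
    stop("exactly one of `preset` or `paths` must be supplied")
  stopifnot(min_valid_fraction > 0, min_valid_fraction <= 1,
            fold_threshold >= 0, fold_threshold <= 1,
            retain_fraction >= 0, retain_fraction <= 1,
            rho_threshold >= 0, rho_threshold <= 1,
            auc_threshold >= 0, auc_threshold <= 1,
            misclass_threshold >= 0, misclass_threshold <= 1,
            min_models >= 1)
  structure(list(preset = preset, paths = paths,
                 min_valid_fraction = min_valid_fraction,
                 impute_shift_sd = impute_shift_sd,
                 impute_width_sd = impute_width_sd,
                 n_permutations_fdr = as.integer(n_permutations_fdr),
                 select_scheme = select_scheme, eval_scheme = eval_scheme,
                 n_bootstrap = as.integer(n_bootstrap),
                 fold_threshold = fold_threshold,
                 retain_fraction = retain_fraction,
                 target_fraction = target_fraction,
                 rho_threshold = rho_threshold,
                 auc_threshold = auc_threshold,
                 misclass_threshold = misclass_threshold,
                 min_models = as.integer(min_models),
                 model_config = model_config,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Validate pipeline input files
#'
#' Checks sample-id alignment across the protein TSV, clinical CSV and
#' label CSV, the label vocabulary, and strict positivity of raw
#' intensities. Never mutates the inputs.
#'
#' @param paths named list with `proteins`, `clinical`, `labels` (and
#'   optionally `clinical_meta`).
#' @return list `ok` (logical) and `problems` (character vector).
#' @export
validate_inputs <- function(paths) {
  problems <- character(0)
  prot <- tryCatch(read_protein_tsv(paths$proteins),
                   error = function(e) {
                     problems <<- c(problems, conditionMessage(e)); NULL
                   })
  clin <- tryCatch(read_clinical_csv(paths$clinical, paths$clinical_meta),
                   error = function(e) {
                     problems <<- c(problems, conditionMessage(e)); NULL
                   })
  labels <- tryCatch(read_labels_csv(paths$labels),
                     error = function(e) {
                       problems <<- c(problems, conditionMessage(e)); NULL
                     })
  if (!is.null(prot) && !is.null(clin) && !is.null(labels)) {
    sp <- rownames(prot$values); sc <- rownames(clin$values)
    sl <- labels$sample_id
    for (pair in list(c("clinical", "proteins"), c("labels", "proteins"))) {
      a <- switch(pair[1], clinical = sc, labels = sl)
      b <- sp
      extra <- setdiff(a, b); miss <- setdiff(b, a)
      if (length(extra) > 0)
        problems <- c(problems, paste0("sample(s) in ", pair[1],
                                       " but not in proteins: ",
                                       paste(extra, collapse = ", ")))
      if (length(miss) > 0)
        problems <- c(problems, paste0("sample(s) in proteins but not in ",
                                       pair[1], ": ",
                                       paste(miss, collapse = ", ")))
    }
    bad_grp <- setdiff(unique(labels$group), group_levels())
    if (length(bad_grp) > 0)
      problems <- c(problems, paste0("unknown group label(s): ",
                                     paste(bad_grp, collapse = ", ")))
    if (anyDuplicated(sl))
      problems <- c(problems, "duplicated sample ids in labels")
  }
  list(ok = length(problems) == 0, problems = problems)
}

load_inputs <- function(config) {
  if (!is.null(config$preset)) {
    generate_cohort(preset_config(config$preset), seed = config$seed)
  } else {
    rep <- validate_inputs(config$paths)
    if (!rep$ok)
      stop("input validation failed: ", paste(rep$problems, collapse = "; "))
    read_cohort_paths(config$paths)
  }
}

read_cohort_paths <- function(paths) {
  structure(list(
    proteins = read_protein_tsv(paths$proteins),
    clinical = read_clinical_csv(paths$clinical, paths$clinical_meta),
    labels = read_labels_csv(paths$labels)),
    class = "cohort_bundle")
}

#' Run the full stratification pipeline
#'
#' Executes, per data modality (clinical-only, proteomic-only, combined):
#' proteomic post-processing and differential testing, clinical kNN
#' imputation, consensus feature selection, five-classifier evaluation,
#' dual-comparison AUC panel filtering (proteomic markers), and consensus
#' misclassification re-stratification. All three modalities share the
#' same schemes and seeds so their comparison isolates the data source.
#' Writes every result table plus a machine-readable manifest and a
#' human-readable summary into `out_dir`; a rerun from the same config is
#' byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage logging.
#' @return `out_dir`, invisibly; the result objects as the attribute
#'   `results`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("[load] resolving inputs")
  bundle <- load_inputs(config)
  labels <- bundle$labels
  y <- labels$group

  say("[prep] proteomics chain (log2 -> filter %.0f%% -> impute %.1f/%.1f -> quantile)",
      100 * config$min_valid_fraction, config$impute_shift_sd,
      config$impute_width_sd)
  prot <- prep_protein_matrix(bundle$proteins,
                              min_fraction = config$min_valid_fraction,
                              shift_sd = config$impute_shift_sd,
                              width_sd = config$impute_width_sd,
                              seed = child_seed(config$seed, 1L))
  say("[prep] %d protein(s) retained", ncol(prot$values))

  say("[test] permutation-FDR differential testing, %d shuffles",
      config$n_permutations_fdr)
  comparisons <- list(c("AT", "CTRL"), c("AT", "DLP"), c("DLP", "CTRL"))
  diff_res <- do.call(rbind, lapply(seq_along(comparisons), function(i)
    permutation_fdr_ttest(prot, labels, comparisons[[i]],
                          n_permutations = config$n_permutations_fdr,
                          seed = child_seed(config$seed, 10L + i))))
  write_differential_csv(diff_res, file.path(out_dir, "differential.csv"))

  say("[prep] clinical kNN imputation (k = 5)")
  clin <- knn_impute(bundle$clinical, k = 5)
  X_clin <- stratification_inputs(clin)
  X_prot <- prot$values
  X_comb <- cbind(X_clin, X_prot[match(rownames(X_clin), rownames(X_prot)), ,
                                 drop = FALSE])
  modalities <- list(clinical = X_clin, proteomic = X_prot,
                     combined = X_comb)
  models <- build_classifiers(config$model_config)

  panels <- list(); metrics <- list(); strata <- list(); mms <- list()
  for (mod in names(modalities)) {
    Xm <- modalities[[mod]]
    say("[select:%s] consensus selection (%dx%d CV, %d bootstraps)", mod,
        config$select_scheme$n_repeats, config$select_scheme$n_folds,
        config$n_bootstrap)
    panel <- select_consensus_features(
      Xm, y, scheme = config$select_scheme,
      fold_threshold = config$fold_threshold,
      n_bootstrap = config$n_bootstrap,
      target_fraction = config$target_fraction,
      rho_threshold = config$rho_threshold,
      models = models, seed = child_seed(config$seed, 20L))
    say("[select:%s] %d feature(s) in panel", mod, nrow(panel))
    eval_feats <- if (nrow(panel) > 0) panel else colnames(Xm)
    say("[bench:%s] evaluating 5 classifiers (%dx%d CV)", mod,
        config$eval_scheme$n_repeats, config$eval_scheme$n_folds)
    metric <- evaluate_models(Xm, y, panel = eval_feats,
                              scheme = config$eval_scheme, models = models,
                              seed = child_seed(config$seed, 30L))
    say("[restratify:%s] misclassification consensus", mod)
    mm <- misclassification_probability(Xm, y, models = models,
                                        scheme = config$eval_scheme,
                                        modality = mod,
                                        seed = child_seed(config$seed, 40L))
    strat <- consensus_reassign(mm, threshold = config$misclass_threshold,
                                min_models = config$min_models)
    panels[[mod]] <- panel; metrics[[mod]] <- metric
    mms[[mod]] <- mm; strata[[mod]] <- strat
  }

  say("[panel] dual-comparison AUC filter (> %.2f) on proteomic markers",
      config$auc_threshold)
  comb_panel <- panels$combined
  candidates <- intersect(panel_features(comb_panel), colnames(X_prot))
  if (length(candidates) == 0) candidates <- colnames(X_prot)
  roc_filter <- filter_panel_by_auc(X_prot, labels, candidates,
                                    threshold = config$auc_threshold)
  comparison <- compare_modalities(strata)

  # ---- emit tables -------------------------------------------------------
  panel_df <- do.call(rbind, lapply(names(panels), function(mod) {
    p <- as.data.frame(panels[[mod]])
    if (nrow(p) == 0) return(NULL)
    cbind(modality = mod, p)
  }))
  utils::write.csv(panel_df, file.path(out_dir, "panels.csv"),
                   row.names = FALSE)
  metric_df <- do.call(rbind, lapply(names(metrics), function(mod)
    cbind(modality = mod, as.data.frame(metrics[[mod]]))))
  utils::write.csv(metric_df, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(roc_filter$results, file.path(out_dir, "roc_results.csv"),
                   row.names = FALSE)
  mis_df <- do.call(rbind, lapply(names(mms), function(mod)
    stratification_long_table(mms[[mod]], strata[[mod]],
                              threshold = config$misclass_threshold)))
  utils::write.csv(mis_df, file.path(out_dir, "misclass.csv"),
                   row.names = FALSE)
  strat_df <- do.call(rbind, lapply(names(strata), function(mod)
    cbind(modality = mod, as.data.frame(strata[[mod]]))))
  utils::write.csv(strat_df, file.path(out_dir, "stratification.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "stratomics",
    version = as.character(utils::packageVersion("stratomics")),
    config = serialize_config(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summary_lines <- c(
    sprintf("stratomics pipeline run (seed %d)", config$seed),
    sprintf("samples: %s", paste(names(table(y)), table(y), sep = "=",
                                 collapse = ", ")),
    sprintf("proteins retained after %.0f%% filter: %d",
            100 * config$min_valid_fraction, ncol(prot$values)),
    sprintf("differential (q < %.2f): %s", 0.05,
            paste(vapply(split(diff_res$significant, diff_res$comparison),
                         sum, numeric(1)),
                  names(split(diff_res$significant, diff_res$comparison)),
                  collapse = ", ")),
    sprintf("panel sizes: %s",
            paste(names(panels), vapply(panels, nrow, numeric(1)),
                  sep = "=", collapse = ", ")),
    sprintf("AUC-filtered proteomic markers (> %.2f in both AT comparisons): %s",
            config$auc_threshold,
            if (length(roc_filter$retained) > 0)
              paste(roc_filter$retained, collapse = ", ") else "(none)"),
    sprintf("misclassification rates: %s",
            paste(comparison$rates$modality,
                  sprintf("%.2f%%", comparison$rates$rate),
                  sep = "=", collapse = ", ")))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  say("[done] %s (%.1fs)", out_dir,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))

  res <- list(bundle = bundle, proteins = prot, differential = diff_res,
              panels = panels, metrics = metrics, roc_filter = roc_filter,
              misclass = mms, strata = strata, comparison = comparison)
  out <- out_dir
  attr(out, "results") <- res
  invisible(out)
}

serialize_config <- function(config) {
  c(config[setdiff(names(config), c("select_scheme", "eval_scheme"))],
    list(select_scheme = unclass(config$select_scheme),
         eval_scheme = unclass(config$eval_scheme)))
}

#' Re-run a pipeline from its manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir output directory for the re-run.
#' @param quiet suppress logging.
#' @return `out_dir`, invisibly.
#' @export
run_from_manifest <- function(manifest_path, out_dir, quiet = FALSE) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cf <- man$config
  # JSON has no NULL scalar: absent/empty fields come back as empty lists
  blank2null <- function(x) if (is.null(x) || length(x) == 0) NULL else x
  config <- run_config(
    preset = blank2null(cf$preset), paths = blank2null(cf$paths),
    min_valid_fraction = cf$min_valid_fraction,
    impute_shift_sd = cf$impute_shift_sd,
    impute_width_sd = cf$impute_width_sd,
    n_permutations_fdr = cf$n_permutations_fdr,
    select_scheme = do.call(cv_scheme, as.list(cf$select_scheme)[c("n_repeats", "n_folds", "stratified", "seed")]),
    eval_scheme = do.call(cv_scheme, as.list(cf$eval_scheme)[c("n_repeats", "n_folds", "stratified", "seed")]),
    n_bootstrap = cf$n_bootstrap,
    fold_threshold = cf$fold_threshold,
    retain_fraction = cf$retain_fraction,
    target_fraction = cf$target_fraction,
    rho_threshold = cf$rho_threshold,
    auc_threshold = cf$auc_threshold,
    misclass_threshold = cf$misclass_threshold,
    min_models = cf$min_models,
    model_config = if (length(cf$model_config) > 0) cf$model_config else list(),
    seed = cf$seed)
  run_pipeline(config, out_dir, quiet = quiet)
}
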