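#' @useDynLib stratomics, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom plogis qlogis sd var cor quantile
#'   pchisq pnorm pt median predict glm binomial coef optim setNames
#'   kruskal.test chisq.test aggregate
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a root seed and an offset; stays below 2^31.
child_seed <- function(seed, offset) {
  as.integer(((as.double(seed) %% 1000003) * 10007 + offset) %% 2147483647)
}

#' Configuration of a synthetic clinical-proteomic cohort
#'
#' Describes the stochastic world a synthetic cohort is drawn from: three
#' diagnosis groups (healthy controls CTRL, dyslipidemic DLP, atherosclerotic
#' AT), log-normal protein intensities with a small set of group-discriminant
#' markers, correlated protein clusters, intensity-dependent (MNAR) plus
#' uniform (MCAR) missingness, and clinical features with group-shifted
#' means. Effects are additive on the log2 scale, in units of the
#' within-group SD.
#'
#' @param group_sizes named integer vector of samples per group.
#' @param n_proteins number of quantified proteins.
#' @param n_clinical number of numeric clinical features.
#' @param n_binary_clinical number of binary (risk-factor style) clinical
#'   features, encoded 0/1.
#' @param n_excluded_clinical number of treatment-style binary columns that
#'   are flagged `excluded` (never used as stratification inputs).
#' @param panel_spec data.frame (`feature`, `target_group`, `effect_size`,
#'   `direction`) of injected marker effects; `effect_size` in within-group
#'   SD units, `direction` is `"up"` or `"down"` in the target group.
#' @param offpanel_spec optional data.frame, same shape: disease-associated
#'   background effects that are NOT part of the biomarker panel (dropped
#'   when an external cohort is generated with `panel_effects_only`).
#' @param base_log2_mean grand mean of log2 LFQ intensity (serum DIA data
#'   typically centres in the low/mid 20s).
#' @param base_log2_sd within-group biological + technical SD on log2 scale.
#' @param protein_mean_spread SD of per-protein baseline log2 means
#'   (abundance dynamic range); must be > 0 for MNAR to be intensity-graded.
#' @param cluster_spec list of `list(members = <features>, rho = <cor>)`
#'   entries; members share a latent factor giving pairwise correlation rho.
#' @param mnar_steepness,mnar_midpoint logistic censoring parameters:
#'   P(missing | x) = plogis(-(x - midpoint) * steepness) on log2 intensity.
#' @param mcar_rate uniform missing-completely-at-random rate on proteins.
#' @param clinical_missing_rate MCAR rate on clinical cells.
#' @param seed root seed; every draw flows from it.
#' @return a validated `synthetic_config` object.
#' @export
synthetic_config <- function(group_sizes = c(CTRL = 66L, DLP = 55L, AT = 60L),
                             n_proteins = 300L,
                             n_clinical = 20L,
                             n_binary_clinical = 4L,
                             n_excluded_clinical = 2L,
                             panel_spec = default_panel_spec(),
                             offpanel_spec = NULL,
                             base_log2_mean = 24,
                             base_log2_sd = 1,
                             protein_mean_spread = 2.5,
                             cluster_spec = default_cluster_spec(),
                             mnar_steepness = 1.0,
                             mnar_midpoint = 20.0,
                             mcar_rate = 0.02,
                             clinical_missing_rate = 0.05,
                             seed = 20180101L) {
  cfg <- list(group_sizes = group_sizes, n_proteins = as.integer(n_proteins),
              n_clinical = as.integer(n_clinical),
              n_binary_clinical = as.integer(n_binary_clinical),
              n_excluded_clinical = as.integer(n_excluded_clinical),
              panel_spec = panel_spec, offpanel_spec = offpanel_spec,
              base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
              protein_mean_spread = protein_mean_spread,
              cluster_spec = cluster_spec,
              mnar_steepness = mnar_steepness, mnar_midpoint = mnar_midpoint,
              mcar_rate = mcar_rate,
              clinical_missing_rate = clinical_missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

default_panel_spec <- function(effect_size = 2.0) {
  data.frame(
    feature = c("marker_up_01", "marker_up_02", "marker_dn_01",
                "marker_dn_02", "marker_dn_03", "marker_dn_04"),
    target_group = "AT",
    effect_size = effect_size,
    direction = c("up", "up", "down", "down", "down", "down"),
    stringsAsFactors = FALSE)
}

default_cluster_spec <- function() {
  list(list(members = c("prot_010", "prot_011", "prot_012"), rho = 0.8),
       list(members = c("prot_020", "prot_021"), rho = 0.9))
}

validate_spec_df <- function(spec, what) {
  if (is.null(spec)) return(invisible(TRUE))
  need <- c("feature", "target_group", "effect_size", "direction")
  if (!all(need %in% names(spec)))
    stop(what, " must have columns ", paste(need, collapse = ", "))
  if (!all(spec$direction %in% c("up", "down")))
    stop(what, ": direction must be 'up' or 'down'")
  invisible(TRUE)
}

validate_synthetic_config <- function(cfg) {
  gs <- cfg$group_sizes
  if (is.null(names(gs)) || any(gs <= 0)) stop("group_sizes must be a named vector of positive counts")
  if (cfg$n_proteins <= 0 || cfg$n_clinical < 0) stop("counts must be positive")
  rates <- c(cfg$mcar_rate, cfg$clinical_missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]")
  for (cl in cfg$cluster_spec)
    if (cl$rho < 0 || cl$rho >= 1) stop("within-cluster correlation must lie in [0,1)")
  validate_spec_df(cfg$panel_spec, "panel_spec")
  validate_spec_df(cfg$offpanel_spec, "offpanel_spec")
  feat_names <- synthetic_feature_names(cfg)
  all_feats <- c(feat_names$proteins, feat_names$clinical)
  spec_feats <- c(cfg$panel_spec$feature, cfg$offpanel_spec$feature)
  missing <- setdiff(spec_feats, all_feats)
  if (length(missing) > 0)
    stop("configuration error: spec features not generated (n_proteins too small?): ",
         paste(missing, collapse = ", "))
  cl_feats <- unlist(lapply(cfg$cluster_spec, `[[`, "members"))
  if (length(setdiff(cl_feats, feat_names$proteins)) > 0)
    stop("cluster members must be generated protein features")
  invisible(cfg)
}

# Feature naming: injected markers first, then generic proteins; clinical
# numerics, binary risk factors, then excluded treatment columns.
synthetic_feature_names <- function(cfg) {
  spec_prot <- unique(c(cfg$panel_spec$feature, cfg$offpanel_spec$feature))
  spec_prot <- spec_prot[!grepl("^(clin|risk|treat)_", spec_prot)]
  n_generic <- cfg$n_proteins - length(spec_prot)
  if (n_generic < 0)
    stop("configuration error: more spec'd protein markers than n_proteins")
  pool <- sprintf("prot_%03d", seq_len(cfg$n_proteins))
  generic <- setdiff(pool, spec_prot)[seq_len(n_generic)]
  proteins <- c(spec_prot, generic)
  clinical <- c(sprintf("clin_%02d", seq_len(cfg$n_clinical)),
                if (cfg$n_binary_clinical > 0) sprintf("risk_%02d", seq_len(cfg$n_binary_clinical)),
                if (cfg$n_excluded_clinical > 0) sprintf("treat_%02d", seq_len(cfg$n_excluded_clinical)))
  list(proteins = proteins, clinical = clinical)
}

effect_offset <- function(spec, feature, group, unit) {
  if (is.null(spec)) return(0)
  hit <- spec$feature == feature & spec$target_group == group
  if (!any(hit)) return(0)
  s <- spec[which(hit)[1], ]
  sign <- if (s$direction == "up") 1 else -1
  sign * s$effect_size * unit
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort bundle (raw protein matrix, clinical table, labels)
#' from a [synthetic_config()]. Log2 intensities are Normal with per-protein
#' baselines, additive group effects on injected markers, and a shared
#' latent factor inside declared correlation clusters; missingness is
#' logistic-MNAR in log2 intensity plus uniform MCAR; clinical features are
#' standard-normal (numeric) or Bernoulli (binary) with group shifts, with
#' MCAR missing cells. Fully reproducible given the seed.
#'
#' @param config a `synthetic_config`.
#' @param cohort cohort label stamped on every sample.
#' @param seed optional override of `config$seed`.
#' @return a `cohort_bundle`: list with `proteins` (`protein_matrix`, state
#'   raw), `clinical` (`clinical_table`), `labels` (data.frame) and `config`.
#' @export
generate_cohort <- function(config, cohort = "discovery", seed = NULL) {
  validate_synthetic_config(config)
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  with_seed(seed, {
    gs <- config$group_sizes
    groups <- rep(names(gs), times = gs)
    n <- length(groups)
    sample_ids <- sprintf("%s_S%03d", substr(cohort, 1, 3), seq_len(n))
    nm <- synthetic_feature_names(config)
    p <- length(nm$proteins)

    # latent standardized protein noise, with cluster factors
    z <- matrix(rnorm(n * p), n, p, dimnames = list(sample_ids, nm$proteins))
    for (cl in config$cluster_spec) {
      f <- rnorm(n)
      for (mname in cl$members)
        z[, mname] <- sqrt(cl$rho) * f + sqrt(1 - cl$rho) * z[, mname]
    }
    mu <- rnorm(p, config$base_log2_mean, config$protein_mean_spread)
    names(mu) <- nm$proteins
    # injected markers emulate reliably quantified serum proteins: their
    # baseline abundance sits one spread above the grand mean, so they are
    # not censored out of the cohort before the analysis even starts
    spec_prot <- intersect(unique(c(config$panel_spec$feature,
                                    config$offpanel_spec$feature)),
                           nm$proteins)
    mu[spec_prot] <- config$base_log2_mean + config$protein_mean_spread
    x <- sweep(z * config$base_log2_sd, 2, mu, `+`)
    for (j in nm$proteins) {
      for (g in names(gs)) {
        d <- effect_offset(config$panel_spec, j, g, config$base_log2_sd) +
          effect_offset(config$offpanel_spec, j, g, config$base_log2_sd)
        if (d != 0) x[groups == g, j] <- x[groups == g, j] + d
      }
    }
    # missingness: logistic MNAR on log2 intensity, then uniform MCAR
    p_mnar <- plogis(-(x - config$mnar_midpoint) * config$mnar_steepness)
    miss <- matrix(runif(n * p) < p_mnar, n, p)
    miss <- miss | matrix(runif(n * p) < config$mcar_rate, n, p)
    raw <- 2^x
    raw[miss] <- NA_real_

    # clinical: numeric N(shift, 1); binary Bernoulli with logit shifts
    ncl <- length(nm$clinical)
    cv <- matrix(NA_real_, n, ncl, dimnames = list(sample_ids, nm$clinical))
    types <- rep("numeric", ncl)
    excluded <- rep(FALSE, ncl)
    for (jj in seq_len(ncl)) {
      f <- nm$clinical[jj]
      if (grepl("^clin_", f)) {
        shift <- vapply(groups, function(g)
          effect_offset(config$panel_spec, f, g, 1) +
            effect_offset(config$offpanel_spec, f, g, 1), numeric(1))
        cv[, jj] <- rnorm(n, mean = shift, sd = 1)
      } else {
        types[jj] <- "binary"
        base_logit <- qlogis(0.25)
        if (grepl("^treat_", f)) {
          excluded[jj] <- TRUE
          # treatment uptake rises sharply with disease stage, like
          # lipid-lowering therapy in a vascular cohort
          prev <- c(CTRL = 0.10, DLP = 0.55, AT = 0.70)[groups]
          prev[is.na(prev)] <- 0.25
          cv[, jj] <- rbinom(n, 1, prev)
        } else {
          shift <- vapply(groups, function(g)
            effect_offset(config$panel_spec, f, g, 1) +
              effect_offset(config$offpanel_spec, f, g, 1), numeric(1))
          cv[, jj] <- rbinom(n, 1, plogis(base_logit + shift))
        }
      }
    }
    if (config$clinical_missing_rate > 0) {
      cm <- matrix(runif(n * ncl) < config$clinical_missing_rate, n, ncl)
      cv[cm] <- NA_real_
    }
    meta <- data.frame(feature = nm$clinical, type = types,
                       excluded = excluded, stringsAsFactors = FALSE)
    labels <- data.frame(sample_id = sample_ids, group = groups,
                         cohort = cohort, stringsAsFactors = FALSE)
    structure(list(proteins = protein_matrix(raw, "raw"),
                   clinical = clinical_table(cv, meta),
                   labels = labels,
                   config = config, seed = seed),
              class = "cohort_bundle")
  })
}

#' Generate an external validation cohort
#'
#' Same generative model as [generate_cohort()] but labeled
#' `cohort = "external"`. With `panel_effects_only = TRUE` (the default,
#' emulating targeted validation of a biomarker panel) any background
#' (`offpanel_spec`) group effects are dropped so that only the declared
#' panel members carry signal.
#'
#' @param config a `synthetic_config`.
#' @param panel_effects_only drop off-panel background effects.
#' @param seed optional seed override.
#' @return a `cohort_bundle` with `cohort == "external"`.
#' @export
generate_external_cohort <- function(config, panel_effects_only = TRUE, seed = NULL) {
  if (panel_effects_only) config$offpanel_spec <- NULL
  generate_cohort(config, cohort = "external", seed = seed)
}

#' Shipped cohort presets
#'
#' `"paper_discovery"` mirrors the discovery-phase structure this pipeline
#' targets: groups CTRL/DLP/AT of 66/55/60 samples, 300 quantified proteins,
#' a 6-member injected marker panel (2 up-, 4 down-regulated in AT at 2 SD),
#' two correlated protein clusters, and clinical features with group shifts.
#' `"paper_external"` is the matching external validation preset with groups
#' 19/24/30.
#'
#' @param name preset name.
#' @return a `synthetic_config`.
#' @export
preset_config <- function(name = c("paper_discovery", "paper_external")) {
  name <- match.arg(name)
  # background disease effects: modest proteomic shifts (never dual-AUC
  # discriminant) plus strong dyslipidemia-defining clinical lipid shifts —
  # the DLP group is diagnosed by lipid thresholds, so its clinical
  # separation is essentially definitional
  offpanel <- data.frame(
    feature = c("prot_001", "prot_002", "prot_003", "clin_01", "clin_02",
                "clin_03", "clin_04", "risk_01"),
    target_group = c("AT", "AT", "DLP", "AT", "AT", "DLP", "DLP", "AT"),
    effect_size = c(0.6, 0.6, 0.6, 1.2, 0.9, 2.0, 1.5, 1.5),
    direction = c("up", "down", "up", "up", "up", "up", "up", "up"),
    stringsAsFactors = FALSE)
  switch(name,
    paper_discovery = synthetic_config(
      group_sizes = c(CTRL = 66L, DLP = 55L, AT = 60L),
      offpanel_spec = offpanel),
    paper_external = synthetic_config(
      group_sizes = c(CTRL = 19L, DLP = 24L, AT = 30L),
      offpanel_spec = offpanel,
      seed = 20180102L))
}

#' Write / read a cohort bundle as plain-text files
#'
#' Writes `proteins.tsv` (protein matrix dialect), `clinical.csv` plus
#' `clinical_meta.csv`, and `labels.csv` into `dir`.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if absent).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   `cohort_bundle` (without the generating config).
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_protein_tsv(bundle$proteins, file.path(dir, "proteins.tsv"))
  write_clinical_csv(bundle$clinical, file.path(dir, "clinical.csv"),
                     file.path(dir, "clinical_meta.csv"))
  write_labels_csv(bundle$labels, file.path(dir, "labels.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  structure(list(
    proteins = read_protein_tsv(file.path(dir, "proteins.tsv")),
    clinical = read_clinical_csv(file.path(dir, "clinical.csv"),
                                 file.path(dir, "clinical_meta.csv")),
    labels = read_labels_csv(file.path(dir, "labels.csv"))),
    class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  tab <- table(x$labels$group)
  cat(sprintf("<cohort_bundle> %s cohort: %s\n",
              x$labels$cohort[1],
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  print(x$proteins)
  print(x$clinical)
  invisible(x)
}
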