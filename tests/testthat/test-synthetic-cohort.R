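test_that("presets reproduce the target group sizes", {
  b <- generate_cohort(preset_config("paper_discovery"))
  tab <- table(b$labels$group)
  expect_equal(unname(tab[c("CTRL", "DLP", "AT")]), c(66L, 55L, 60L),
               ignore_attr = TRUE)
  expect_equal(ncol(b$proteins$values), 300L)
  expect_true(all(b$labels$cohort == "discovery"))

  e <- generate_external_cohort(preset_config("paper_external"))
  tabe <- table(e$labels$group)
  expect_equal(unname(tabe[c("CTRL", "DLP", "AT")]), c(19L, 24L, 30L),
               ignore_attr = TRUE)
  expect_true(all(e$labels$cohort == "external"))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthetic_config(group_sizes = c(CTRL = 10L, DLP = 10L, AT = 10L),
                          n_proteins = 40L, n_clinical = 5L)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$proteins$values, b2$proteins$values)
  expect_identical(b1$clinical$values, b2$clinical$values)
  expect_identical(b1$labels, b2$labels)
  b3 <- generate_cohort(cfg, seed = 99L)
  expect_false(identical(b1$proteins$values, b3$proteins$values))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(mcar_rate = 1.5), "rates")
  expect_error(synthetic_config(
    cluster_spec = list(list(members = c("prot_001", "prot_002"), rho = 1))),
    "correlation")
  expect_error(synthetic_config(
    n_proteins = 4L, cluster_spec = list(),
    panel_spec = data.frame(feature = sprintf("m%d", 1:6), target_group = "AT",
                            effect_size = 2, direction = "up")),
    "configuration error")
})

test_that("MNAR missingness decreases with protein mean intensity", {
  cfg <- synthetic_config(group_sizes = c(CTRL = 60L, DLP = 60L, AT = 60L),
                          n_proteins = 200L, n_clinical = 2L,
                          panel_spec = default_panel_spec()[0, ],
                          cluster_spec = list(), mcar_rate = 0,
                          clinical_missing_rate = 0, seed = 11L)
  b <- generate_cohort(cfg)
  v <- b$proteins$values
  mean_log2 <- colMeans(log2(v), na.rm = TRUE)
  miss <- colMeans(is.na(v))
  bins <- cut(mean_log2, quantile(mean_log2, seq(0, 1, 0.2)),
              include.lowest = TRUE)
  binned <- tapply(miss, bins, mean)
  expect_true(all(diff(binned) <= 0.02))  # non-increasing up to binning noise
  expect_gt(binned[1], binned[length(binned)])
})

test_that("cluster correlations and injected effects are recoverable", {
  cfg <- synthetic_config(
    group_sizes = c(CTRL = 60L, DLP = 60L, AT = 60L), n_proteins = 60L,
    n_clinical = 2L,
    panel_spec = data.frame(feature = c("mk_up", "mk_dn"), target_group = "AT",
                            effect_size = 1.5, direction = c("up", "down")),
    cluster_spec = list(list(members = c("prot_005", "prot_006", "prot_007"),
                             rho = 0.8)),
    mnar_steepness = 1, mnar_midpoint = 5,  # effectively no censoring
    mcar_rate = 0, clinical_missing_rate = 0, seed = 21L)
  b <- generate_cohort(cfg)
  x <- log2(b$proteins$values)
  cc <- cor(x[, c("prot_005", "prot_006", "prot_007")])
  off <- cc[upper.tri(cc)]
  expect_true(all(abs(off - 0.8) < 0.1))

  grp <- b$labels$group
  for (f in c("mk_up", "mk_dn")) {
    d <- mean(x[grp == "AT", f]) - mean(x[grp != "AT", f])
    want <- if (f == "mk_up") 1.5 else -1.5
    expect_lt(abs(d - want * cfg$base_log2_sd), 0.25 * cfg$base_log2_sd)
  }
})

test_that("external cohort with empty panel carries no class signal", {
  cfg <- synthetic_config(group_sizes = c(CTRL = 30L, DLP = 30L, AT = 30L),
                          n_proteins = 30L, n_clinical = 4L,
                          panel_spec = default_panel_spec()[0, ],
                          offpanel_spec = data.frame(
                            feature = "prot_001", target_group = "AT",
                            effect_size = 3, direction = "up"),
                          cluster_spec = list(), mnar_steepness = 1,
                          mnar_midpoint = 5, mcar_rate = 0,
                          clinical_missing_rate = 0, seed = 5L)
  e <- generate_external_cohort(cfg, panel_effects_only = TRUE)
  x <- log2(e$proteins$values)
  grp <- e$labels$group
  # the off-panel effect must have been dropped
  d <- mean(x[grp == "AT", "prot_001"]) - mean(x[grp != "AT", "prot_001"])
  expect_lt(abs(d), 0.75)  # ~3 SE at n=30/group, vs injected 3 SD
  # cross-validated classifier AUC near chance on pure noise
  rep <- evaluate_models(x, grp, scheme = cv_scheme(2, 3, seed = 2),
                         models = build_classifiers(names = "NB"))
  expect_lt(abs(rep$value[rep$metric == "auc_macro_ovr"] - 0.5), 0.12)
})

test_that("cohort bundles round-trip through the text formats", {
  cfg <- synthetic_config(group_sizes = c(CTRL = 8L, DLP = 8L, AT = 8L),
                          n_proteins = 20L, n_clinical = 4L,
                          cluster_spec = list())
  b <- generate_cohort(cfg)
  d <- tempfile()
  write_cohort(b, d)
  b2 <- read_cohort(d)
  expect_equal(b2$proteins$values, b$proteins$values, tolerance = 1e-10)
  expect_equal(b2$clinical$values, b$clinical$values, tolerance = 1e-10)
  expect_identical(b2$labels, b$labels)
  unlink(d, recursive = TRUE)
})
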