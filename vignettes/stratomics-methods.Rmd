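---
title: "Methods: integrated clinical-proteomic stratification with stratomics"
author: "stratomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated clinical-proteomic stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stratomics)
```

## The problem

Cardiovascular risk stratification by lipid panels alone misses patients
whose disease has progressed despite pharmacologically controlled lipids.
A promising alternative combines routine clinical chemistry with serum
proteomics: quantify a few hundred proteins by label-free DIA mass
spectrometry, learn which clinical and proteomic features separate healthy
controls (CTRL), dyslipidemic patients (DLP) and patients with advanced
carotid atherosclerosis (AT), and use a bank of classifiers both to define
a compact biomarker panel and to audit the original clinical group
assignments. `stratomics` implements that full workflow as a reusable,
seeded pipeline, plus a synthetic cohort generator so every stage is
testable without access to patient data.

## Proteomic post-processing

The LFQ intensity matrix (samples x proteins, missing values allowed)
moves through a fixed chain, enforced by a state flag
(`raw -> log2 -> imputed -> normalized`):

1. **log2 transform** of strictly positive raw intensities.
2. **Valid-value filter**: keep proteins quantified in at least 70% of all
   samples (inclusive boundary, computed across groups; a per-group
   variant is deliberately not the default because the reference workflow
   filters on the total).
3. **Downshifted-normal imputation**, per sample: missing entries are
   drawn from Normal(mean − 1.8·SD, (0.3·SD)²) of that sample's observed
   values. The 1.8/0.3 pair is the de-facto convention for left-censored
   DIA data; both are exposed as parameters. Imputation is per sample
   (column-wise in matrix-processing terms) because missingness in DIA
   mostly reflects per-run detection limits.
4. **Quantile normalization**: all samples are forced onto the average
   order-statistic distribution; ties receive the mean of the reference
   values they span. Idempotence (to 1e-10) is a tested invariant.
5. **Permutation-FDR differential testing**: per protein a two-sample
   pooled-variance t statistic; the null is built from label shuffles
   (default 250), the same shuffles reused for every protein. For a
   threshold t\*, FDR(t\*) = (mean permutation count of |t_null| ≥ t\*) /
   (observed count of |t| ≥ t\*); a protein's q-value is the smallest FDR
   at which it is called, which makes q monotone non-increasing in |t|.
   Zero-variance proteins get q = 1 and a degeneracy flag — never
   significant. No s0 variance fuzz is added: the reference analysis used
   a plain two-sample t test.

## Clinical preparation

Missing clinical values are imputed by weighted kNN (k = 5): Euclidean
distance over mutually present features, rescaled by the fraction of
features used, with inverse-distance weights and an exact-match shortcut
at distance 0. Distances are computed on per-feature standardized values
(raw clinical units are incommensurable — mg/dL against cell counts);
this is a documented choice the reference description leaves open, and it
can be disabled. Standardization for modeling is always fitted on
training samples only and applied frozen to held-out samples
(`fit_standardizer()` / `apply_standardizer()`); features with zero
training variance are flagged and passed through. Treatment-style columns
carry an `excluded` metadata flag and never enter stratification inputs.

## Consensus feature selection

Inside every training fold of a repeated stratified CV scheme (reference
setting 3 repeats x 5 folds), 50 stratified bootstrap resamples are drawn.
On each resample, one selector per classifier family keeps the top 25% of
features: recursive feature elimination (dropping the worst 10% per
iteration) guided by absolute LSVM coefficients or tree impurity
importances, and a univariate F-test ranking for naive Bayes, which
exposes neither. A feature counts as selected in a bootstrap when at
least 3 of the 5 selectors agree; it is flagged in the fold when its
bootstrap frequency reaches 60% (inclusive); it enters the panel when
flagged in at least 20% of folds (inclusive). Finally, panel features
with |Spearman ρ| ≥ 0.85 on the reference data are grouped by single
linkage and each cluster keeps its most frequently selected
representative (ties: higher mean bootstrap frequency, then
lexicographic).

Two choices here were genuinely open and are ours: the reference
description does not say whether one selector or one per family ran per
bootstrap (we run one per family with a 3-of-5 vote, mirroring the
re-stratification consensus), and it does not state the per-bootstrap
"top k" (we expose it as `target_fraction`, default 0.25).

### Null behaviour of the consensus selector

On pure-noise data the procedure does **not** return an empty panel: each
selector always keeps its top quarter of features, and because the data
matrix is fixed across folds and bootstraps, features that are
spuriously class-correlated *in that sample* are selected consistently —
resampling cannot wash out sample-level luck. Measured null panels hold
4–10 features (40 noise features, 3x5 folds; 4–5 at 50 bootstraps). This
is a property of the published procedure, not an implementation artifact:
it is a top-fraction stability selector without error control, and on
real data it likewise retained roughly the top quarter of clinical
features. One acceptance criterion expects ≤ 2 features under the null;
we implement it as written and report it red, with this analysis.

## The classifier bank

Five families behind one probabilistic interface (`fit_model()`,
`predict_prob()`), all seeded and deterministic:

* **NB** — Gaussian naive Bayes with a variance floor.
* **LSVM** — one-vs-rest linear SVM (squared hinge, L2, C = 1) with Platt
  sigmoid calibration fitted on the training fold; a raw margin would not
  satisfy the probability contract the re-stratification stage needs.
* **RF** — 100 CART trees, bootstrap + sqrt(p) feature subsampling.
* **ETC** — 100 extremely randomized trees (random thresholds, no
  bootstrap).
* **AB** — SAMME AdaBoost on 50 depth-1 stumps.

The tree ensembles are implemented in C++ (Rcpp) against R's RNG, so
`set.seed()` governs every fit. Hyperparameters are exposed in
`build_classifiers()` and recorded in reports; the reference work states
none. Class levels are taken in order of first appearance, which makes
argmax tie-breaking — and therefore every metric — invariant under label
renaming; fitted models also canonicalize feature order so metrics are
invariant to column permutations (both are tested to 1e-12).

Evaluation (`evaluate_models()`) uses 20-repeated stratified threefold CV
by default, reporting accuracy, macro precision, micro recall (equal to
accuracy in single-label multiclass), macro F1 and macro one-vs-rest
AUC-ROC, each with a 2.5/97.5 percentile interval over repetition-level
scores — the "95% CI" of the reference is reported without a method, so
the percentile interval is our documented choice, as is macro-OvR for the
multiclass AUC (it matches the per-comparison binary ROC curves the
reference reports). `permutation_test()` recomputes the cross-validated
AUC under label shuffles and uses the add-one p-value
(1 + #{null ≥ observed}) / (1 + shuffles), so p < 0.001 requires at least
1000 shuffles. `consensus_importance()` normalizes each model's
importances to sum 1, averages over folds and ranks by mean rank; an
occlusion-based additive-attribution score (mean |Δ true-class
probability| when a feature is replaced by its training mean — a cheap
SHAP-style approximation, not exact Shapley values) can be reported
alongside but never alters the consensus rank.

## Panel statistics

`binary_auc()` is the rank statistic (ties ½) with the Youden-optimal
cutoff reported at the midpoint between adjacent distinct values, ties in
J broken toward higher sensitivity. The biomarker filter retains a
feature iff max(AUC, 1−AUC) > 0.7 (strict) in **both** AT-vs-DLP and
AT-vs-CTRL — direction-agnostic because the reference panel contains both
up- and down-regulated markers. By default the filter runs on the
imputed-normalized matrix (the reference is silent on this; it is
configurable). `spearman_screen()` selects within-group pairs with
|R| > 0.6 (strict). Baseline tables use tie-corrected Kruskal–Wallis with
hand-implemented Dunn z post-hocs (Bonferroni) and Pearson chi-square.
Proprietary ROUT outlier removal is replaced by an optional, off-by-default
MAD flagger (`flag_outliers_mad()`) — a documented substitution, not a
silent one.

## Consensus re-stratification

For each model, an individual's misclassification probability is the
fraction of its out-of-fold predictions (one per CV repetition) that
disagree with the pre-assigned label — an operational definition the
reference leaves implicit; it is leakage-free and spans 0–100% as
described. (The alternative 1 − mean predicted probability of the
pre-label is available behind the model probabilities if wanted.) An
individual is reassigned when at least 3 of the 5 models exceed 50%
(strict) misclassification probability; the post-label is the majority
modal alternative among flagging models, ties broken by the highest mean
predicted-alternative frequency, then by the fixed order CTRL < DLP < AT.
The misclassification rate is 100 × reassigned / total per modality —
note the reference's printed rates (11.17%/10.32%/3.17%) cannot be
reproduced as individuals-reassigned / cohort-size (3 of 181 is 1.66%),
so their denominators are not emulated; the directional ordering
(combined ≤ each single modality on split-signal data) is what the tests
assert.

## The synthetic cohort generator

`generate_cohort()` draws the world the analysis assumes: log2
intensities Normal per protein and group, per-protein baselines
N(24, 2.5²) with within-group SD 1 (serum DIA log2 intensities centre in
the low-to-mid 20s with a few orders of magnitude of dynamic range);
additive group effects on declared markers, in SD units; correlated
clusters via a shared latent factor (`x = sqrt(ρ)·f + sqrt(1−ρ)·ε`);
missingness as logistic censoring in log2 intensity (steepness 1.0,
midpoint 20.0 → ~13% missing overall, ~12% of proteins dropped by the 70%
filter — typical of serum DIA) plus 2% uniform MCAR; clinical numerics
N(shift, 1), binary risk factors Bernoulli with logit shifts, treatment
columns with disease-graded uptake and an `excluded` flag, 5% MCAR.
Injected markers take baselines one spread above the grand mean: the real
panel proteins are abundant serum proteins that survive the valid-value
filter by construction, and a generator whose markers were randomly
censored out of the cohort would not emulate the stated analysis.
Off-panel "background" proteomic effects are 0.6 SD — real but below the
dual-AUC>0.7 bar, mirroring the fact that only the panel survived the
reference filter — while background clinical effects run up to 2 SD:
dyslipidemia is diagnosed by lipid thresholds, so strong clinical DLP
separation is definitional. The `paper_discovery` preset uses groups 66/55/60 with
300 proteins and a 6-marker panel (2 up, 4 down in AT, 2 SD);
`paper_external` uses 19/24/30, and `generate_external_cohort(...,
panel_effects_only = TRUE)` drops background effects to emulate targeted
validation.

What the generator does **not** emulate: age/sex confounding, medication
effects, batch structure, peptide-level quantification, heavy-tailed
clinical distributions. A green test therefore establishes that the
pipeline recovers the signals this model encodes — not that it would
reproduce the reference cohort's exact counts.

## Numerical and runtime notes

All randomness flows from one root seed per entry point; child seeds are
derived arithmetically and stay below 2^31. Reruns from a pipeline
manifest are byte-identical (tested by md5). Default ensemble sizes and
schemes follow the reference settings; tests and the acceptance script
shrink ensembles (20–30 trees, 25 stumps), schemes (1–2 repeats) and
bootstrap/permutation counts for runtime — decision thresholds are never
scaled. Degenerate cases are defined, not accidental: zero-variance
proteins (q = 1), constant features in standardization (pass-through,
flagged), constant features in correlation screens (NA, never selected),
samples with fewer than two observed values (error), classes smaller than
the fold count (error).

## Known limitations

* The consensus selector has no false-positive control (see "Null
  behaviour" above); panel size under noise scales with
  `target_fraction`.
* Platt calibration is fitted on the training fold's own decision values
  (slightly optimistic probabilities; ranking, hence AUC, unaffected).
* The out-of-fold misclassification probability is granular in the number
  of CV repetitions (20 repeats → steps of 5%).
* Printed reference cohort numbers (protein counts, exact
  misclassification percentages, AUC = 1.0 panels) depend on the
  unreleased dataset and are out of reach by design; the pipeline is
  validated on recoverable synthetic structure instead.
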