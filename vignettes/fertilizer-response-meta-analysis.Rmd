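---
title: "Methods: meta-analysis of maize fertilizer response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of maize fertilizer response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frmeta)
```

`frmeta` synthesizes on-farm maize fertilizer trials from Sub-Saharan
Africa: each record is one treatment–control pair of mean yields with
replicate counts, a variance statistic, the N rate, and soil/climate/
management covariates. This vignette is the package's own account of the
statistical choices: the models, their assumptions, the tunable
parameters, what the synthetic generator does and does not emulate, and
the known limitations.

## Data model and harmonization

The canonical record (`trial_schema()`) keeps yields in kg ha⁻¹, total
C and N in g kg⁻¹, extractable P in mg kg⁻¹, exchangeable cations in
cmol kg⁻¹, texture in percent, rainfall in mm per growing season.
Harmonization (`harmonize()`) is declarative: multiplicative unit rules
are supplied as configuration (e.g. t ha⁻¹ → ×1000), not hard-coded,
with two exceptions that are fixed constants of the field's soil-test
literature: extractable P measured by Bray is placed on the Olsen scale
as P-Olsen = 0.44·P-Bray1 and P-Olsen = 0.79·P-Bray2. These two assays
are never both measured in the same experiment, so a single `p_olsen`
column (with a provenance flag for converted values) carries all P
information; if a record nonetheless arrives with both, the measured
Olsen value wins and a warning is raised — a measured value beats a
derived one. Soil-order labels are deliberately *not* validated against
an official WRB vocabulary: source databases mix WRB and legacy USDA
names (including misspellings), and silently "correcting" them would
fabricate information. An optional user-supplied mapping table relabels
them instead.

## The missing-data cascade

Order is fixed and re-running the cascade on its own output is a no-op:

1. **Variance recovery** (`recover_sd()`): a reported sd is kept;
   otherwise sd = se·√n; otherwise sd = CV·mean/100.
2. **The 1.5× rule** (`impute_missing_sd()`): records with no variance
   statistic at all receive 1.5 times the mean of all reported sds,
   pooled over both arms of the whole dataset. The multiplier
   penalizes non-reporting (imputed records get larger variances, hence
   smaller weights) and is configurable (`sd_multiplier`).
3. **Correlation-gated linear imputation**
   (`plan_linear_imputation()`): soil-property pairs with Pearson
   r > 0.8 (on pairwise-complete cases; the gate applies to r itself by
   default, to |r| via `use_abs_r` since soil properties can correlate
   negatively) are paired greedily by descending |r|, each variable in
   at most one pair. The member with more missing values is dropped
   from later analysis, after an OLS line fit on complete pairs fills
   the kept member's gaps where the partner is observed. Ties in
   missing counts drop the variable later in the canonical column
   ordering — an arbitrary but deterministic rule.
4. **Predictive mean matching** (`pmm_impute()`) for whatever gaps
   remain: chained equations over the configured variables; each sweep
   regresses the target on the others on complete data, draws the
   coefficient vector from its estimated sampling distribution (the
   standard stochastic step that keeps imputations from collapsing to
   the regression line), and fills each missing case with the observed
   value of a donor drawn uniformly from the k nearest predicted
   means. Defaults k = 5 donors and 10 sweeps are the common PMM
   choices, and a single completed dataset (m = 1) is produced because
   the downstream analysis is a single analysis of one database, not a
   pooled multiple-imputation inference. All PMM randomness is governed
   by one seed; by construction every imputed value is an observed
   value of the same variable, so imputation can never extend a
   variable's support.

## Effect sizes and responsiveness

ln FR = ln(x̄_t/x̄_c) with delta-method variance
v = sd_t²/(n_t x̄_t²) + sd_c²/(n_c x̄_c²). The variance formula is the
first-order approximation for a ratio of independent means; it is exact
only in the limit of small CVs, a point that matters below. N-AE =
(x̄_t − x̄_c)/FN is reported descriptively only — it is a rate, not an
effect size with a defined sampling variance, so it never enters the
meta-analytic weighting. Records with FN = 0 get a missing N-AE rather
than an error: unfertilized controls are simply not efficiency-scored.

Responsiveness: FR > 1 responsive; FR ≤ 1 (boundary inclusive, so
FR = 1 exactly is non-responsive) is split by the control yield at
1125 kg ha⁻¹ — the smallholder benchmark for the region — into fertile
vs poor non-responsive soils. The threshold is configurable because the
benchmark is region-specific.

## Random-effects meta-analysis

The intercept-only model ln FR_i ~ N(μ, v_i + τ²) is fitted by REML.
Because the model has a single variance parameter, optimization is a
bounded one-dimensional search of the restricted log-likelihood on
τ² ∈ [0, max(10·var(y), 10·max v_i)] with tolerance 1e-8 and an
explicit boundary check at τ² = 0 (interior search alone can miss the
boundary maximum for homogeneous data). The test suite verifies the
optimum against a two-stage dense grid search to 1e-6. μ and its
standard error use weights 1/(v_i + τ²); CIs use the normal multiplier
z₀.₉₇₅ = 1.959964 rather than a t quantile, matching the convention of
reporting plain 95% intervals at the k's typical of this literature.
Heterogeneity is summarized by Cochran's Q_T with fixed-effect weights
1/v_i and a χ²(k−1) reference; no I² is derived from it.

Each observation — not each study — is treated as an independent
record, following the practice of accepting multiple entries per
experiment in literature syntheses. No cluster-robust correction is
applied. Consequence: when heterogeneity truly lives at the study
level, the observation-level τ̂² estimates the realized between-record
variance, which is deflated relative to the study-level variance by the
finite-cluster factor (N − Σm_j²/N)/(N − 1) for cluster sizes m_j —
about 1–4% at this database's shape. The parameter-recovery tests
account for exactly this geometry.

**Subgroups**: per level of a categorical moderator,
ln FR_w = Σw_i ln FR_i/Σw_i with the *fixed-effect* weights w_i = 1/v_i
— the printed formula of the synthesis tradition this package follows —
with a random-effects weighting 1/(v_i + τ̂²) available behind the
`weights = "random"` switch. A level "differs from no effect" iff its
CI excludes ln FR = 0; two levels differ iff their CIs are disjoint.
CI-disjointness is conservative relative to a Wald test on the
difference; it is used because it is the decision rule this literature
reports.

**Publication bias**: the Egger-type test is the weighted regression of
effect on standard error with weights 1/v_i, z = slope/se(slope),
two-sided normal p. Trim-and-fill uses the L0 estimator: rank-based
count k0 of suppressed studies about the fixed-effect center, trimming
and re-centering until k0 stabilizes (iteration cap 50), then filling
mirror images and re-pooling with fixed-effect weights. The side is
auto-detected from the skew of effects about the fixed-effect center
(configurable). Note a known behavior, visible in the synthetic runs:
under strong genuine heterogeneity trim-and-fill reads spread as
asymmetry and can impute a substantial k0 even without any suppression;
k0 is reported as a diagnostic, never as a correction applied to the
headline estimate.

## Regression and variable importance

Predictors that are right-skewed (total C, P-Olsen, N rate,
exchangeable K, silt, rainfall) are natural-log transformed; soil pH
and clay are not. The recipe is configuration, not code, because
sources differ on whether pH should be logged; the default follows the
fitted-model convention rather than prose descriptions. All predictors
are then scaled by their sample sd *without centering* — the scaling
equalizes representation across predictors while leaving t statistics
and p-values identical to the unstandardized fit (verified by test).
GLMs are OLS with intercept via `stats::lm`; when N-AE is the response
the N rate is barred from the predictor set, since it is the response's
own denominator. No multiple-testing correction is applied across
coefficients; raw significance codes are reported.

VIP scores come from an in-package NIPALS PLS1 decomposition:
VIP_j = √(p·Σ_a SS_a (w_aj/‖w_a‖)² / Σ_a SS_a), with SS_a the
y-variance captured by component a. Σ_j VIP_j² = p holds by
construction and is asserted in tests, along with the closed form
VIP = √p for a single informative predictor under orthonormal X and
agreement with an independent PLS implementation. The component count
is chosen by leave-one-out cross-validated prediction error, capped at
min(p, 10) — the literature rarely states its choice, so the package
makes a defensible one explicit. Predictors with VIP > 1 are flagged
important.

The FR-vs-control-yield curve FR = a·yield^b is fitted by OLS on the
log-log scale, i.e. a multiplicative-error model consistent with the
log-scale analysis elsewhere in the pipeline (nonlinear least squares
on the original scale would instead assume additive error on FR).
Because ln FR = ln x̄_t − ln x̄_c is regressed on ln x̄_c, measurement
error in the control mean induces a small division bias in b̂ of order
var(noise)/var(ln yield) — about 0.01–0.03 here; any analysis of this
kind on real trial data carries the same bias.

## The synthetic generator

`synthetic_config()` defaults are chosen once to mirror the conditions
of the on-farm trial literature the package targets: 70 studies with
3–10 observations each (~457 records), 44% Kenyan, N rates uniform on
15–150 kg N ha⁻¹, soil pH ~ N(5.2, 0.5), control yields log-normal
(median 1500 kg ha⁻¹, sdlog 0.55), pooled effect true_mu = log(1.8),
study-level τ² = 0.15, control-yield exponent −0.5, NPK records 16%
with a +0.35 ln FR shift, within-plot CVs log-normal around 15%,
variance reported as sd/se/CV/nothing for 50/15/15/20% of records, and
per-variable missingness rates of 5–30% mirroring the gappiness of
published soil descriptions. Moderator effects act on centered
covariates so true_mu stays the marginal mean; every latent value is
written to a ground-truth sidecar, and a deletion log makes
imputation-accuracy scoring possible.

Publication bias, when enabled, censors records with probability
increasing as the *studentized* effect z = ln FR/se falls below a
threshold — the classic suppression-of-non-significant-results
mechanism. Censoring on the raw effect alone was rejected at design
time: with τ² an order of magnitude above the typical sampling
variance, raw-effect censoring is nearly independent of each record's
se and leaves the funnel symmetric, so no funnel-based diagnostic could
ever see it; significance-based censoring is both the more realistic
mechanism and the one the diagnostics are built to detect.

What the generator does **not** emulate: spatial or temporal
correlation of covariates, weather time series, non-random study
placement, reporting heterogeneity in units (inputs are generated
already canonical), and real soil-taxonomy structure (labels are drawn
independently of the covariates). Passing tests therefore demonstrate
the pipeline's statistical correctness under its stated model, not that
real trial databases satisfy that model.

## Problem sizes and numerical choices

The test suite runs REML-vs-grid checks on k ≤ 10 instances, the Q_T
size check with 1000 homogeneous replicates at k = 25, Egger power on
20 generated databases of ~250 records, and full parameter recovery
(μ, τ²) on 200 seeded databases of ~500 observations plus power-law
recovery on 50 — sizes chosen so each property is measured with
adequate Monte-Carlo precision on a single CPU. Degenerate inputs are
errors, not silent results: zero variances in weighting, constant
columns in standardization, all-equal standard errors in the Egger
design, fewer observed values than PMM donors.

## Limitations

- Observation-level independence is assumed throughout; with few, large
  studies the pooled se is anti-conservative and τ̂² deflated (see
  above).
- The delta-method variance understates uncertainty at large CVs or
  tiny replicate counts.
- The 1.5× sd rule is a blunt instrument: it penalizes non-reporting
  but ignores the correlation between yield level and sd.
- Trim-and-fill conflates heterogeneity with asymmetry; interpret k0
  qualitatively.
- PMM with m = 1 understates imputation uncertainty in downstream
  standard errors; the package reports provenance flags so sensitivity
  analyses can exclude imputed records.
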