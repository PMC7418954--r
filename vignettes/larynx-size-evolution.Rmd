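---
title: "Phylogenetic comparative analysis of larynx-size evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic comparative analysis of larynx-size evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`laryngevol` implements a complete comparative pipeline for asking how a
morphological trait — here, overall larynx size — evolves against body size
across two mammalian orders: landmark morphometrics, a principal-component
size axis, phylogenetic regression, grade-shift inference, evolutionary-rate
comparison, and acoustic/social correlates. This vignette explains the
models, the estimation choices, and the synthetic data that make every stage
testable without the original specimens.

## The measurement layer

Each larynx is summarized by 10 Euclidean distances (mm) between pairs of 14
anatomical landmarks on the cricoid, thyroid, and arytenoid cartilages and
the hyoid (`landmark_distances()`; vocal fold length averages the right and
left vocal-process distances). Distances are invariant to how the specimen
was oriented during scanning, which is why the pipeline starts from
interlandmark distances rather than raw coordinates.

Because laryngeal dimensions scale proportionally, all analyses use log10
measurements. `size_axis()` runs a PCA on the *correlation* matrix of the 10
log10 columns and keeps the leading component as "larynx size". Three
conventions matter downstream and are fixed here:

* loadings are standardized (eigenvector × √eigenvalue), so a loading is the
  correlation between the component and the variable;
* the axis is sign-oriented so the mean loading is positive (larger scores =
  larger larynges);
* scores are standardized to unit variance. Slope magnitudes in every
  regression are relative to this convention; `scores = "raw"` switches to
  the eigenvector-projection scale for reconciliation with analyses that
  used unstandardized scores.

With a single retained component, a varimax rotation is the identity, so no
rotation step exists. Coefficients of variation (`cv()`) use the n−1 sample
SD on *raw* (not log) values, the convention for ranking measurement
variability.

## Phylogenetic regression

The workhorse is `pgls()`: generalized least squares whose error covariance
is the Brownian-motion tree covariance \(V\) (shared root-to-ancestor path
lengths, `vcv_bm()`) with off-diagonals damped by Pagel's λ
(`apply_lambda()`). λ is profiled over [0, 1] by golden-section search
(tolerance 1e-6, boundaries checked); the fit at the optimum is obtained by
Cholesky whitening. Estimation is ML so that log-likelihoods of nested mean
structures are comparable; σ² is reported as the ML estimate e′V⁻¹e/n, while
standard errors and t statistics use the unbiased e′V⁻¹e/(n−p) with n−p
degrees of freedom. Degrees of freedom are reported as (n, n−p); printed df
conventions differ across the literature, and t values, not df labels, are
the comparable surface.

"Residual larynx size" (`residual_trait()`) is the raw-scale residual of the
λ-ML regression of size scores on log10 body length across all species — the
working trait for shift detection, rate comparison, and the phenogram.
Branch lengths are treated as absolute time (My) throughout; the two clade
trees are joined at a configurable root age (`graft_trees()`, default 79 My,
a conventional primate–carnivoran split). Because the clades share no
post-root history, cross-clade covariances are zero and cross-order
statistics are insensitive to the root age (tested at 70 and 90 My in the
suite via the zero-covariance property).

Units: body length is stored in mm and regressions use log10(mm).
Intercepts shift by −slope per decade, so analyses that report intercepts on
a log10(cm) scale differ by exactly the slope; slopes are unit-free.

## Grade shifts

Two complementary routes detect shifts in mean relative larynx size.

**pANCOVA** (`pancova()`): nested λ-GLS models compared by an F test on
whitened residual sums of squares — slopes (`y ~ x*g` vs `y ~ x+g`), then
intercepts (`y ~ x+g` vs `y ~ x`). λ is profiled once on the full model and
held fixed across the pair so both models see the same error structure. The
λ profile inside `pancova()` uses REML by default: with a deep grouping
factor in the design, the ML profile underestimates λ often enough to push
the test's type-I error a few points above nominal (measured 8.75% vs a
5% ± 2 calibration band over 400 null replicates), while the REML profile
restores 6.25%, indistinguishable from using the true λ. Reported model
log-likelihoods remain ML everywhere.

**Multi-regime OU** (`ou_regime_fit()`, `detect_shifts()`): trait evolution
with attraction strength α toward regime-specific optima θ, one shared α and
σ² across regimes. Tip expectations are the Hansen weights of the optima
along each root-to-tip path (root state = root regime's optimum); the tip
covariance is the fixed-root OU covariance. Given α, the optima profile out
by GLS and σ² analytically, so the ML search is one-dimensional in log α
(default range 1e-6/T to 50/T for tree depth T; boundary hits are warned).
The α → 0 Brownian limit is computed through `expm1`, so it is exact rather
than special-cased.

`detect_shifts()` is a forward stepwise search over all edges. Design
choices:

* the model-selection criterion is BIC + 2·log C(E, k) — a configuration
  penalty for the number of ways k shifts can be placed on E edges. The
  weight-2 default was set against the search's false-positive calibration
  (≤ 10% spurious detections on no-shift Brownian data): the stepwise
  search maximizes over ~E candidate edges, which plain BIC (or a weight-1
  penalty) does not account for (measured 58% false positives at weight 1,
  7.5% at weight 2 on pure-birth trees);
* scanning every candidate at the incumbent α reduces each candidate to one
  cheap GLS solve; the top five scanned edges are then refit with α
  re-optimized and the accept/reject decision uses the refit criterion.
  The fixed-α scan alone can mis-rank terminal-edge shifts near the
  Brownian boundary, which is why it is a screen, not the final score;
* ties break toward the rootward edge; the search is deterministic;
* a shift on a root-child edge is identifiable only up to its complement
  (repainting the other side of the root gives the same tip partition), so
  recovery and bootstrap support treat sibling root edges as equivalent
  placements.

`shift_support()` is a parametric bootstrap: simulate from the fitted model,
rerun the search, and report the percentage of replicates recovering each
shift (or an adjacent edge). `snr()` is the package's effect size for a
fitted shift model: the Mahalanobis norm, under the fitted OU covariance, of
the shift-induced deviation of tip expectations from the best single-regime
mean. It is linear in the optimum differences, inversely proportional to the
stationary SD √(σ²/2α), and 0 for a single regime; published
signal-to-noise variants differ in normalization, so cross-tool numerical
identity is not expected, but the >1 = "high power" reading carries over.

`grade_magnitude()` quantifies a grade shift in raw units: greedy
nearest-neighbour matching (no replacement) of cross-clade species pairs on
body length, then the per-pair mean ratio of the 10 raw measurements. The
pair list is part of the result because the matching rule, not just the
ratio, determines reproducibility.

## Evolutionary rates

Under Brownian motion the n−1 standardized independent contrasts
(`pic_contrasts()`, Felsenstein pruning via `ape`) are i.i.d. N(0, σ²), so
the mean squared contrast within a monophyletic clade is its ML rate
(`clade_rate()`, trait-units²/My). `rate_ratio_test()` tests whether clade
A's rate exceeds clade B's: squared contrasts are pooled — exchangeable
under a common rate — and reassigned at the observed counts; the one-tailed
P uses the add-one correction. This permutation scheme is this package's
definition of the test; published rate-comparison tools differ in how they
build the null, so P values are expected to be close but not
digit-identical across implementations. `rate_posterior()` gives the Bayesian complement
under the Jeffreys prior 1/σ²: a scaled inverse-χ² sampled directly, for
posterior-density plots.

`trait_vs_body_rate()` compares two traits' rates on the same tips in the
same units (log10 larynx dimension vs log10 body length, both mm): ratio of
mean squared contrasts with a paired permutation that swaps the two traits'
squared contrasts within each node.

`ancestral_states()` produces the phenogram: each branch is stretched by its
rate (clade-level rates from the detected regimes via `clade_edge_rates()` —
a declared simplification of per-branch multiple-variance methods, so the
phenogram is qualitative), then exact GLS ancestral estimates are computed
on the rescaled tree and plotted against node heights from the original
tree.

A caveat that the test suite quantifies: the clade rate ratio from ~25
contrasts per clade has a log-scale SD of about 0.35 even under pure
Brownian motion, and any i.i.d. (non-phylogenetic) residual component —
λ < 1 or measurement noise — inflates short-branch contrasts and widens it
further. Point estimates of a true 2.17× contrast therefore scatter roughly
between 1× and 4× at this sample size; the permutation *test* stays
calibrated, but the estimate is not precise.

## Acoustics and sociality

`f0_allometry()` regresses log10 mean call fundamental frequency on size
scores by λ-ML pGLS, per clade, excluding (and naming) species without
usable F0; `f0_slope_comparison()` compares clade slopes by pANCOVA.
`ols_r2()`, `mann_whitney()`, `spearman_cor()` are deliberately
*non*-phylogenetic, matching standard practice for these comparisons; the
Mann–Whitney U is the exact first-sample statistic (midranks, with
U_a + U_b = n_a·n_b asserted on every call) with exact small-sample P and a
tie-corrected normal approximation otherwise. `group_dispersion()` reports
both the unscaled median-absolute-deviation-about-the-median and the mean
absolute deviation about the mean: "MAD" is used ambiguously for skewed
group-size data in the comparative literature (an unscaled
median-about-median can never exceed the median itself on nonnegative data,
which published dispersion values sometimes do), so both variants are
returned and neither is privileged. `assign_group_size()` encodes the
cleaning rules: stated mean wins, solitary → 1, breeding pair → 2, else the
range midpoint.

## The synthetic study

`simulate_study()` generates everything the pipeline consumes, as a pure
function of `simulation_config(seed = ...)`. Defaults describe the study
regime the package targets:

| parameter | default | meaning |
|---|---|---|
| tips | 26 + 29 | species per clade |
| root age / crown ages | 79 / 65 / 55 My | joined root, clade depths |
| allometric slope | 4.71 | size score per log10 mm |
| intercept difference | 1.05 | grade shift, score units |
| residual λ | 0.95 | phylogenetic signal of residuals |
| residual rates | 2.17 : 1 | clade rate contrast (9e-4 score²/My base) |
| landmark noise CV | 0.1 | per-coordinate lognormal noise |
| F0 slope / noise SD | −0.476 / 0.4 | log10 Hz per score unit |
| group sizes | lognormal, medians 13.8 / 2.6 | per clade |

Body length evolves by Brownian motion on the log10 scale (rate 5e-4/My
around 2.8, i.e. ~630 mm), spanning roughly an order of magnitude across
tips — the regime in which a slope of 4.71 against unit-variance scores is
self-consistent. Landmarks scale the fixed 14-point template isotropically
(log10 scale = 1.3 + 0.3 × size score, so raw-measurement CVs land near the
0.6–0.9 range) with i.i.d. lognormal coordinate noise. The noise CV of 0.1
keeps the leading PC above 90% of variance while staying small enough not to
contaminate contrast-based rate estimation; pushing PC1 down to exactly
~91% would require ~0.2 of *i.i.d.* noise, which is not what the residual
(structured, phylogenetic) variance in real morphometric data looks like and
degrades every tip-level rate statistic. What passing tests on these data do
**not** show: robustness to structured shape variation (allometric shape
change, clade-specific landmark geometry), intraspecific sampling error, or
non-ultrametric trees — none of which the generator emulates.

Simulation problem sizes in the test-and-acceptance suite — 55-tip trees,
60–150 replicates per recovery scenario, 500 replicates per calibration,
permutation counts of 199–9999 — were chosen as the smallest sizes at which
the Monte-Carlo error is clearly smaller than the tolerance being asserted.

## Numerical choices and degenerate inputs

* All covariance solves go through Cholesky factors; non-PD matrices abort.
* λ and α optimizations check boundary values explicitly; boundary fits are
  returned with a warning, not an error.
* Zero-length terminal branches with unequal tip values make contrasts
  infinite and abort; polytomies are resolved to zero-length edges with a
  warning.
* Singular designs abort naming the collinear columns; constant covariates
  after listwise deletion abort.
* Ultrametricity is checked within 1e-6 of tree depth and warned about,
  never enforced.
* Missing covariates are dropped listwise per model with the n logged,
  mirroring per-covariate sample sizes in real analyses.

## Known limitations

* One specimen per species: no within-species (measurement-error) model.
* The OU machinery shares α and σ² across regimes; only optima shift.
* The phenogram's branch rates are clade-level, not per-branch.
* The rate-ratio point estimate is wide at n ≈ 55 (see above); report it
  with its permutation P, not alone.
* Tip-label matching is string-based with a user-supplied synonym map; no
  taxonomic name resolution is attempted.
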