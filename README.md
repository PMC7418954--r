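# laryngevol

Phylogenetic comparative analysis of larynx-size evolution.

## The problem

Across mammals, the larynx sets the voice: bigger larynges carry longer
vocal folds and lower fundamental frequencies. Whether larynx size simply
tracks body size — or whether some clades have escaped that allometric
constraint — is a question about *grade shifts* (changes in the intercept
of a log–log allometry on parts of a phylogeny) and *evolutionary rates*
(how fast a trait diversifies per unit time). `laryngevol` implements the
full comparative workflow for two-clade designs such as primates versus
carnivorans, for comparative morphologists and bioacousticians who have
per-species landmark or distance data and time-calibrated phylogenies.

The pipeline:

1. **Morphometrics** — 10 interlandmark distances from 14 laryngeal
   landmarks; a correlation-matrix PCA on the log10 distances whose first
   component ("larynx size", PC1) typically captures >90 % of variance.
2. **Allometry** — phylogenetic generalized least squares (pGLS) of PC1 on
   log10 body length with Pagel's λ estimated by maximum likelihood:
   `y = α_clade + β·log10(L) + ε`, `ε ~ N(0, σ²·V(λ))`.
3. **Grade shifts** — phylogenetic ANCOVA (nested λ-GLS F tests on slopes,
   then intercepts); multi-regime Ornstein–Uhlenbeck shift detection
   (`dy = α_sel(θ_regime − y)dt + σ dW`) by stepwise search under a
   pBIC-style criterion, with parametric-bootstrap support and a √ηϕ-type
   signal-to-noise effect size; grade magnitude from body-length-matched
   species pairs.
4. **Rates** — clade-wise Brownian-motion rates from squared independent
   contrasts, a one-tailed permutation test of the rate ratio, scaled
   inverse-χ² posterior rate densities, larynx-vs-body rate comparison,
   and a rate-rescaled ancestral phenogram.
5. **Correlates** — pGLS acoustic allometry of log10 mean F0 on larynx
   size; Mann–Whitney, Spearman and dispersion summaries for social group
   size.

A first-class synthetic-data generator (`simulate_study()`) produces trees,
landmarks, measurements, F0 and ecology columns with the statistical
structure the analysis assumes, so the entire pipeline is testable without
access to any real specimen data.

## Worked example

Everything below is computed from a synthetic study generated at seed 1 —
55 species (26 "primates", 29 "carnivorans") with an injected grade shift
of 1.05 score units, residual λ = 0.95, and a 2.17× clade rate contrast:

```r
library(laryngevol)

sim <- simulate_study(simulation_config(seed = 1))
d   <- sim$specimens

ax <- size_axis(d)                      # PC1 "larynx size"
ax
#> Larynx size axis: PC1 of 10 log10 measurements across 55 species
#>   variance explained: 97.9%   mean loading: 0.990 (SD 0.007)

d$size       <- ax$scores$size
d$log10_body <- log10(d$body_length_mm)

fit <- pgls(size ~ log10_body, d, sim$tree)
fit
#> pGLS fit (n = 55, lambda = 0.9886, ML)
#>             estimate     se        t p
#> (Intercept) -14.7126 0.8782 -16.7541 0
#> log10_body    5.1525 0.2967  17.3679 0
```

The slope (5.15 here) is the allometric exponent in standardized-PC1 units
per decade of body length; λ near 1 says the residuals are strongly
phylogenetically structured. Is there a grade shift between the clades?

```r
pancova(d, sim$tree, predictor = "log10_body", hypothesis = "intercepts")
#> pANCOVA (intercepts): F(1, 52) = 13.2865, P = 0.000618  [lambda = 0.916]
```

Yes: at a common slope, the clade intercepts differ (P < 0.001). The OU
shift search finds the same structure without being told the clades, and a
parametric bootstrap quantifies placement support:

```r
det <- detect_shifts(fit$residuals, sim$tree, max_shifts = 3)
det <- shift_support(det, B = 100, seed = 1)
det
#> OU shift model: 2 regime(s), alpha = 0.02682 (half-life 25.8 My), sigma2 = 0.003256
#>   regime tip means: regime1 = -0.510, regime2 = 0.493
#>   optima: regime1 = -0.510, regime2 = 0.629
#>   shift edges: 1
#>   loglik = 12.883   criterion = -0.373
#>   bootstrap support (%): edge 1: 79
snr(det)
#> [1] 8.08
```

Edge 1 is the primate stem — the detected regime split is exactly the clade
partition, with an effect size (signal-to-noise ratio) of 8.1, far above
the >1 threshold for reliable detection. In raw units, matched
body-length pairs put the shifted clade's larynx at about twice the size:

```r
grade_magnitude(d)
#> Grade magnitude (primate / carnivoran), 8 body-length-matched pairs:
#>   mean ratio = 2.26 (SD = 0.55, range = 1.61-3.15)

rate_ratio_test(fit$residuals, sim$tree,
                d$species[d$clade == "primate"],
                d$species[d$clade == "carnivoran"],
                n_perm = 9999, seed = 1)
#> BM rate ratio: 1.844 (sigma2_a = 0.002731, sigma2_b = 0.001481)
#>   one-tailed permutation P (ratio > 1) = 0.0766  [9999 permutations]
```

The rate ratio estimate (1.84 against a true 2.17) illustrates a point the
methods vignette quantifies: with ~25 contrasts per clade the ratio is an
imprecise estimate even when the test is calibrated — report it with its
permutation P.

`run_all(run_config(...))` chains all of the above (plus covariate models,
F0 allometry and the social-group statistics) into a single report with
deterministic, seed-stamped JSON serialization (`report_json()`), and
`plot_allometry()`, `plot_phenogram()` and the `autoplot()` methods draw
the standard figures.

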