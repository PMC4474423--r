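---
title: "Covariability-based multiple regression: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariability-based multiple regression: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comre)
```

## The question the method asks

Coexpression analysis asks whether two genes' expression levels move
together.  Modulation analysis asks a conditional question: does the
*strength* of that co-movement depend on the expression of a third gene — a
*modulator*?  In breast cancer, for example, the regulatory influence of many
genes on each other is known to differ between estrogen-receptor-high and
-low tumours, making *ESR1* a canonical modulator.  This package addresses
the multi-modulator form of the question: given M candidate modulators, which
of them — singly or jointly — predict the per-sample regulation strength of
each gene pair?

## Covariability: a per-sample measure of regulation strength

A correlation coefficient is a cohort-level summary; modelling its dependence
on modulators requires a per-sample quantity.  The covariability of genes
$i$ and $j$ in sample $k$ is the product of their expression z-scores,

$$C_{ij}^k \;=\; \frac{e_i^k - \mu_i}{\sigma_i}\cdot
                 \frac{e_j^k - \mu_j}{\sigma_j},$$

the per-sample product-moment contribution to the pair's Pearson
correlation.  Positive values of large magnitude mark samples where the two
genes deviate strongly in the same direction; negative values, in opposite
directions.

**The $\sigma$ convention.**  With $\sigma$ taken as the sample standard
deviation (the $K-1$ denominator, as in this package) the identity is

$$\sum_k C_{ij}^k \;=\; (K-1)\,\rho_{ij},$$

not $\rho_{ij}$ itself.  The alternative convention — $\sigma$ as the root
sum of squared deviations — makes the sum equal $\rho$ exactly but bounds
each $|C^k|$ near 1, which is incompatible with the large per-sample
covariability magnitudes (around $\pm 100$ in cohorts of a few hundred
samples) that make the statistic informative as a regressand.  The package
therefore uses the sample-sd convention throughout; `covariability()` and
the tests assert the $(K-1)\rho$ identity at $10^{-10}$.

## The regression model

For each gene pair, the covariability vector is regressed on the
z-transformed expression profiles of the M candidate modulators:

$$C_{ij} \;=\; \beta_0 + \sum_{m\in M}\beta_m\, e_m + \varepsilon .$$

Because each regressor is z-transformed within the cohort, the $\beta_m$
are standardized coefficients, comparable across modulators.  Each
coefficient is tested two-sided with a t-test on $K - M - 1$ degrees of
freedom.  A pair's M-vectors of $\beta$ and p-values form its
*co-modulation pattern*; pairs whose sets of significant modulators
(p < 0.05 by default, strict) coincide form a *co-modulation group*.

**Intercept.**  The literal model above without $\beta_0$ forces the fitted
covariability through zero, but the mean of a covariability vector is
$(K-1)\rho/K$ — nonzero for any correlated pair — so omitting the intercept
biases every slope for such pairs.  The package fits an intercept by
default; `intercept = FALSE` reproduces the no-intercept form, with t-tests
then on $K - M$ degrees of freedom.  Only modulator coefficients are ever
tested.

**Batching.**  The design matrix is shared by all pairs, so
$(X^\top X)^{-1}X^\top$ is computed once and applied to chunked blocks of
covariability vectors (10,000 pairs per chunk by default).  Memory stays
bounded in the chunk size, and an all-pairs scan of several thousand genes
(tens of millions of regressions) is feasible on a single desktop core.
Batched and one-at-a-time fits agree to $10^{-10}$ by test.

**Collinearity.**  The model assumes approximately independent modulators.
A rank-deficient design is a hard error naming the collinear columns, and a
condition number of $X^\top X$ above $10^8$ is likewise an error rather than
a silent regularisation, since ridge-type shrinkage would change the meaning
of the reported $\beta$.

**Degenerate responses.**  A constant covariability vector (possible in
pathological fixtures) yields zero residual variance; coefficients at
rounding-noise scale are then reported with p = 1, exact nonzero fits with
p = 0.

**Random baseline.**  `random_baseline = TRUE` replaces the modulator
columns with seeded i.i.d. standard-normal draws.  On real data this is the
calibration control: each synthetic regressor should come out significant in
roughly 5% of pairs at the 0.05 cutoff, and large deviations would signal a
miscalibrated test rather than biology.

## Downstream analysis

* **Tallies and groups** — `call_significance()` applies the strict
  p < $\alpha$ rule; `modulator_tally()` reports per-modulator counts with
  percentages rounded to two decimals (the conventional reporting
  precision); `group_by_signature()` partitions pairs exhaustively,
  including the explicit `"none"` group, sorted by size with deterministic
  tie-breaks.
* **Core pairs** — for functional interpretation a group is thinned to the
  pairs whose signature-modulator p-values survive Bonferroni adjustment,
  `p × family < α`.  The family size defaults to the number of pairs tested
  — the most conservative reading — and is configurable; with
  `rule = "all"` (default) every signature modulator must pass, `"any"`
  requires one.  The empty signature has no p-values to adjust and is not a
  valid core query.
* **Hubs** — node degree is the count of first-order neighbours within a
  group's pair graph; ties in the hub ranking break lexicographically.
* **Co-occurrence** — whether pairs modulated by one modulator tend also to
  be modulated by another is tested on the 2×2 cross-tabulation with the
  two-sided Fisher exact test, computed by the point-probability rule (the
  sum of hypergeometric probabilities not exceeding the observed table's,
  with the customary $1+10^{-7}$ tie guard; equal to base R's
  `fisher.test`).  Direction is the sign of the observed both-count against
  its hypergeometric expectation; degenerate margins give p = 1 with a
  warning.  `cooccurrence_matrix()` returns the signed $-\log_{10} p$ matrix
  used for heat-map displays.
* **Proportion intervals** — 95% Wald intervals
  $\hat p \pm 1.96\sqrt{\hat p(1-\hat p)/N}$, unclipped unless requested.

## Cross-cohort validation

Patterns learned in a discovery cohort are validated in an independent
cohort by comparing, patient by patient, the *estimated* covariability
profile — discovery $\beta$s applied to the patient's modulator z-scores,
computed within the validation cohort because array scales differ between
cohorts — with the *real* profile computed from the validation cohort's own
expression.  A patient validates when the Pearson correlation across the
pair subset is positive with two-sided p below 0.05, and the validated
proportion is tested against a null proportion with a one-sample z-test,
$z = (\hat p - p_0)/\sqrt{p_0(1-p_0)/N}$.

Three defaults here were genuinely open choices:

* the pair subset is all pairs with at least one significant modulator in
  discovery (restrictable to any group signature, e.g. a specific
  two-modulator group);
* $p_0 = 0.05$, the chance rate of patient-level significance, since only a
  conservative null is defensible without an external estimate;
* "significantly positively correlated" is operationalised as the standard
  two-sided test plus a sign condition, rather than a one-sided test, to
  keep the per-patient p-values comparable with the usual correlation test.

Estimated profiles include the discovery intercept (configurable
implicitly: patterns fitted without an intercept contribute none).

## The synthetic-data generator

`generate_null()` draws i.i.d. Gaussian log2-like expression (mean 8, sd 1,
the typical location and spread of RMA-processed microarray values) — no
structure at all.  `generate_modulated()` implements exactly the generative
model the regression assumes: modulators are i.i.d. standard normal, and
each planted pair's per-sample correlation target is
$\rho_k = \mathrm{clip}(\text{baseline} + \sum_m \beta_m z_m^k)$, clipped to
$(-0.99, 0.99)$ with a warning count, the pair's two values then drawn from
a bivariate normal with correlation $\rho_k$.  A linear link (rather than
e.g. tanh) is deliberate: it matches the regression's linearity assumption,
so parameter-recovery experiments test estimation rather than link
mismatch.  Covariability is a noisy per-sample proxy of $\rho_k$ (its
variance is $1+\rho_k^2$ even at the true parameter), so recovery claims are
distributional across replicate pairs, never per-pair exact.  All draws flow
from the single scenario seed; outputs are bit-identical under a fixed seed.

What the generator does *not* emulate: probe-level artefacts, batch and
platform effects, heavy-tailed or skewed expression, correlated modulators,
and the dense pervasive correlation structure of real tumour cohorts.
Passing tests therefore demonstrate statistical correctness of the
machinery under its own model, not robustness to everything real arrays do.

## Problem sizes used in the packaged experiments

The test-suite and acceptance experiments run at sizes chosen to estimate
each quantity with useful Monte-Carlo precision while remaining quick to
rerun:

* *Null calibration*: 50 genes (1,225 pairs) × 10 null modulator variables
  × 200 samples → 12,250 pooled coefficient tests, giving a binomial
  standard error of about 0.002 on the 0.05 rejection rate.
* *Parameter recovery*: 100 replicate pairs, one modulator with
  $\beta = 0.3$, 300 samples — enough for per-pair power well above one
  half and a clear sign signal.
* *Cross-cohort validation*: 200 planted pairs with baselines spread over
  $(-0.8, 0.8)$ and $\beta = 0.5$ on one of two modulators, 300 samples per
  cohort.  The wide baseline spread matters: per-patient correlations
  compare profiles *across* pairs, so validation power comes from
  between-pair heterogeneity in regulation strength, which real cohorts
  have in abundance and a homogeneous simulation would lack.

## Preprocessing conventions

Probe collapsing keeps, per gene, the probe with the largest coefficient of
variation (sd/mean on the log2 scale); ties break to the lexicographically
smallest probe id.  CV uses the sample (n−1) standard deviation by default;
both conventions are exposed because published pipelines rarely state which
they used.  The noise filter removes rows with CV < 5% or mean < 6 log2
units (strict inequalities on removal), preserves row order, and is
idempotent.  Missing values are rejected at load time rather than imputed:
both the covariability statistic and ordinary least squares assume complete
data, and silent imputation would distort per-sample products.

## Known limitations

* The method measures *modulation* of co-movement, not direct or causal
  regulation; a significant modulator may be a proxy for an unmeasured one.
* Ordinary least squares treats modulators as independent; strongly
  correlated candidate modulators split or mask each other's effects, and
  the package refuses only near-exact collinearity.
* The covariability response is heteroscedastic by construction (variance
  $1+\rho_k^2$), which OLS ignores; coefficient tests remain approximately
  calibrated (verified on null simulations) but are not exact.
* Wald proportion intervals and the one-sample z-test are poor near
  proportions of 0 or 1 with small cohorts; they are kept because they are
  the field's standard report, not because they are optimal.
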