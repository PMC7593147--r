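---
title: "Simulating and treating missing SDs and sample sizes in meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and treating missing SDs and sample sizes in meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(metamiss)
```

## The problem

Weighted meta-analysis needs, for every study, an effect size and its
sampling variance. For the common two-group effect sizes (log response
ratio, Hedges' *d*) the variance is built from the group standard deviations
(SDs) and sample sizes (SSs); for Fisher's *z* it is built from the sample
size alone. Primary studies, however, frequently omit SDs and sometimes
SSs, and the analyst must decide what to do: drop the incomplete studies,
abandon weighting, approximate weights from sample sizes, or impute the
missing values. `metamiss` provides a controlled laboratory for that
decision: it simulates meta-analysis data sets whose complete version is
known, deletes SDs/SSs under specified missingness mechanisms, applies
fourteen treatment options, and measures how far each option's grand mean
and confidence interval drift from the *fully informed* analysis of the
complete data.

## Data-generating model

Two kinds of data sets are generated, each row one hypothetical study:

* **Mean-difference data** (`simulate_md_data()`): control means from a
  truncated normal TN(1, 0.25) bounded below at 0.001, treatment means from
  TN(2, 0.5) likewise; control SDs from TN(0.25, 0.125) and treatment SDs
  from TN(0.5, 0.25), both restricted to [0.01, 1]; group sample sizes from
  a Poisson(10) truncated below at 5. The positive lower bound on the means
  keeps the log response ratio defined; the SD box keeps variances
  plausible; the SS truncation avoids degenerate two-or-three-subject
  studies.
* **Correlation data** (`simulate_cor_data()`): correlation coefficients
  from TN(0.5, 0.125) on [-1, 1] and sample sizes from the same truncated
  Poisson.

Default size is 100 studies per data set and 10 replicate data sets per
kind. Truncated normals are sampled by inverse-CDF on the truncated
probability interval and the truncated Poisson by inverse-CDF through
`qpois`, so draws are exact, vectorized, and byte-reproducible under a
seed. Group draws are independent across and within rows; nothing in the
generator induces publication bias, heteroscedastic designs, or non-normal
outcomes, so conclusions drawn from it speak to well-behaved meta-analytic
data only.

## Missingness mechanisms

`apply_deletion()` blanks `round(fraction * n)` rows' SD pair and/or,
independently, the SS pair — within a row the control and treatment values
always disappear together, as they tend to in practice. Row selection is
weighted sampling without replacement with weights from
`deletion_weights()`:

* **MCAR** — uniform weights.
* **MAR** — weights proportional to the rank position of the effect size
  when effect sizes are ranked in decreasing order: the smaller the effect,
  the likelier its SDs/SSs vanish. Rank itself is used as the weight, the
  minimal scheme that makes the deletion chance increase linearly with rank
  position; ranks tie-break by row order for determinism.
* **MNAR** — weights proportional to the sum of the rank of `sd_c + sd_t`
  (ascending) and the rank of `n_c + n_t` (descending): imprecise, small
  studies lose their values preferentially, a dependence on the missing
  values themselves.
* **corMCAR** — deletion is uniform, but the data set is first re-paired by
  `sort_cormcar()` so that large effect sizes carry small SDs and large
  SSs. The pairing is exact (the three column families are sorted
  independently and zipped), which is the strongest version of the
  scenario; a noisy pairing would sit between this and MCAR. The ordering
  uses the raw log ratio so it does not depend on the SDs being re-paired.

The default fraction grid is `seq(0.1, 0.9, length.out = 16)`. Sixteen
steps spanning 10–90% reproduce the design's factorial count (4 scenarios
x 40 replicate-target combinations x 16 fractions = 2,560 incomplete data
sets, `plan_factorial()`); an even 5% step would need a seventeenth value,
so the grid trades the round step size for the stated span and count. The
grid is an argument, not a constant.

## Effect sizes

`effect_sizes()` computes, per study, the small-sample bias-corrected log
response ratio (with its delta-method variance), Hedges' *d* with the
correction factor `J = 1 - 3/(4(n_c + n_t - 2) - 1)` and variance
`(n_c+n_t)/(n_c n_t) + d^2/(2(n_c+n_t))`, or Fisher's
`z = artanh(r)` with variance `1/(n-3)`. When only sample sizes are
reported, the variance surrogate `(n_t + n_c)/(n_t n_c)`
(`ss_approx_variance()`) can stand in for the true sampling variance.

Where SDs or SSs are missing, the corrected log response ratio is
undefined; treatments that do not need per-study variances (unweighted,
SS-weighted) fall back row-by-row to the simple ratio `ln(m_t/m_c)`. This
mixes corrected and uncorrected values across rows, but the correction is
O(1/n) and small at the simulated sample sizes, and the uncorrected ratio
is the only computable choice for those rows. Hedges' *d* offers no such
fallback — its formula consumes the SDs and SSs themselves — so rows
lacking them are unusable for *d* whatever the treatment, and sample-size
weighting (option 3) is structurally inapplicable to *d*. For Fisher's
*z* the "SS-weighted" option coincides with the natural weighting
`1/(n-3)` on the rows that report `n`, and therefore with complete-case
analysis; it is still emitted so the fourteen-option table stays complete.

## The fourteen treatments

`run_treatment()` applies one of (`treatment_options()`):

1.  complete-case analysis (drop incompletely reported studies);
2.  unweighted analysis (unit variances, every computable effect size);
3.  sample-size-weighted analysis;
4.  mean and 5. median single imputation;
6.  –11. chained-equations multiple imputation with per-variable plug-ins:
    random sample, stochastic ("proper") linear regression, predictive
    mean matching, CART, a 10-tree forest, and Bayesian PMM;
12. bootstrap expectation-maximization under a multivariate normal;
13. iterative random-forest imputation;
14. additive (natural-spline) regression on a bootstrap resample with PMM.

Design choices inside the imputation engine, where the method descriptions
leave latitude:

* **Chained equations** run 5 cycles (the conventional default of the
  chained-equations literature) through the fixed order `sd_t, sd_c, n_t,
  n_c`; missing cells are initialized by random draws from the observed
  values. Because the predictor set is restricted to the fully observed
  columns (group means, or `r`, plus any complete SD/SS columns), the
  cycles converge immediately; they are retained so that order effects can
  be probed (`order` argument). The test suite checks that reversing the
  order shifts pooled grand means by less than statistical noise.
* **PMM** draws one donor uniformly from the 5 observed values whose
  predictions are nearest; 5 donors is the common software default. The
  regression-based plug-ins draw coefficients and the residual variance
  from their normal-inverse-gamma reference posterior, so repeated
  imputations genuinely vary and Rubin's between-imputation variance is
  positive.
* **CART** grows one tree (minimum leaf 5) and draws a donor from the
  missing row's leaf; the forest plug-in grows 10 trees on bootstrap
  resamples and draws a donor from a randomly chosen tree's leaf.
* **Bootstrap EM** resamples rows, runs EM for the multivariate-normal MLE
  over all columns (up to 500 iterations, scale-aware tolerance 1e-6), and
  draws each row's missing cells jointly from their conditional normal;
  cells falling outside the bounds are redrawn from the truncated
  univariate conditional marginal. Above 60% missingness the method
  returns a structured `skipped` record rather than attempting a fit, the
  operational threshold above which this family of algorithms becomes
  unreliable; the cap is configurable. EM non-convergence on a given
  bootstrap is a recorded per-imputation failure, not an exception.
* **Iterative random forest** (100 trees per column) starts from column
  means, uses all other columns as predictors — it is a joint, not a
  chained, method — and stops when the change in imputed values increases,
  returning the previous iteration (at most 10 iterations). Its
  between-imputation variability comes from the forest bootstrap.
* **Bounds**: imputed SDs are restricted to [0.01, 1] and imputed SSs
  rounded to integers `>= 5` (the rounding rule is ours; the bounds
  prevent implausible values and protect downstream model convergence).
  Donor-based methods satisfy the bounds automatically; model-based draws
  are redrawn up to 10 times, then clamped.
* `m = 100` imputations is the default, matching the study design; the
  test suite and acceptance script use `m` of 3–5, which is enough to
  exercise Rubin pooling while keeping runtimes in minutes.

## Estimation and pooling

Every completed (or filtered) data set is fitted with the intercept-only
random-effects model `yi ~ N(mu, vi + tau2)`: tau-squared by REML
(`metafor::rma.uni` stands behind `reml_tau2()` /
`random_effects_fit()`, the same estimator the applied workflow uses), the
grand mean by inverse-variance weighting `w_i = 1/(v_i + tau2)`, and the
95% interval by the normal approximation `mu ± 1.96 se` — no
Knapp–Hartung or Barnard–Rubin adjustment, matching the pooling function
this workflow mirrors. The unweighted option runs the same machinery with
all `v_i = 1`. The test suite cross-checks the REML estimate against a
brute-force golden-section maximization of the restricted likelihood
written independently of the package.

`rubin_pool()` combines the `m` per-imputation fits: pooled mean
`mean(mu_j)`, total variance `mean(se_j^2) + (1 + 1/m) var(mu_j)`, normal
95% interval. Failed imputations are excluded with `m_used` recorded. With
zero missingness every imputation returns the identical data set, the
between-imputation variance is exactly zero, and every treatment
reproduces the fully informed estimate to machine precision — the
zero-deletion identity the acceptance suite asserts at 1e-10.

## Performance measures and the factorial sweep

For each factorial cell, `run_factorial()` computes the deviation of the
treatment's grand mean (estimate minus reference) and of its CI width from
the replicate-matched fully informed analysis — the same complete data
set, re-paired first in the corMCAR scenario, since re-pairing changes the
effect-size/weight alignment and hence the reference itself. Per-cell
seeds are derived by hashing the master seed with the cell coordinates, so
any cell can be reproduced in isolation and reruns are byte-identical.
Cell failures (too few usable rows, non-convergence) become `failed` or
`skipped` records, never abort the sweep. `summarize_deviation()`
averages over replicates only; `plot_deviation()` draws deviation against
the deletion fraction (CI-width curves halved in the plot only, for
legibility). No RMSE-style ranking is computed: the deviations are meant
to be read as trends.

The shipped defaults (`default_config()`) encode the full design — 2,560
incomplete data sets x 14 options x up to 100 imputations — which is a
cluster-scale computation. The bundled checks run scaled-down slices whose
sizes are chosen to keep the whole suite within minutes on one CPU while
still giving the statistical assertions room: 10 replicates at 4 fractions
for the option-1–3 bias/CI checks, 3 replicates at `m = 5` for the
imputation-bias check, 200 and 1,000 replicates for the tau-squared
recovery and coverage simulations.

## Known limitations

* The multiple-imputation methods are faithful to their published
  descriptions, not bit-compatible with the R packages that inspired them;
  tuning constants those packages leave undocumented (chain length, donor
  counts, priors) are fixed here at the conventional values listed above.
* The exact corMCAR pairing is the extreme of its scenario; real data sets
  exhibit noisier effect-size/precision dependence.
* The generator's distributions are unimodal and homoscedastic; wider or
  skewed SD/SS distributions would inflate imputation variability and CI
  widths beyond what these simulations show.
* Bounds are enforced marginally (redraw/clamp, truncated conditional
  marginals in the EM method), not by joint truncated sampling.

## A minimal session

```{r, eval = FALSE}
d   <- simulate_md_data(100, seed = 1)
inc <- apply_deletion(d, "MCAR", target = "SD", fraction = 0.5, seed = 2)
ref <- fully_informed_reference(d, "lnrr")
cc  <- run_treatment(inc, "complete_case", "lnrr")
pmm <- run_treatment(inc, "pmm", "lnrr", m = 100, seed = 3)
c(reference = ref$mu, complete_case = cc$mu, pmm = pmm$mu)
```
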