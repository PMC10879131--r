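---
title: "Methods: wealth- and season-modified WASH effects and gridded burden projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wealth- and season-modified WASH effects and gridded burden projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(washeq)
```

# The scientific problem

Household water, sanitation and handwashing (WASH) interventions are a
central tool against child diarrhea in low-income, climate-sensitive
settings.  Two questions drive this package's design:

1. **Equity**: does a combined WASH intervention reduce diarrhea more, or
   less, among children of the lowest socioeconomic position (SEP)?  SEP
   is measured by an asset-based wealth index, summarized as a *wealth
   rank* in the cumulative distribution of index scores (0 = poorest,
   1 = wealthiest).
2. **Climate**: is the benefit concentrated in the monsoon season, when
   rainfall-driven pathogen transmission raises background risk?

Having answered both on trial data, the package extrapolates the fitted
effect surface to gridded rural populations — combining a wealth-rank
raster, a population raster, an urban mask and district identifiers — to
map where a similar intervention would avert the most cases.

# The statistical models

## Inequality indices (RII/SII)

Within one arm, diarrhea is regressed on wealth rank $r$ with a
log-link binomial GLM, $\log v(r) = \beta_0 + \beta_1 r$.  The Relative
Index of Inequality is the bottom-to-top ratio
$\mathrm{RII} = v(0)/v(1) = e^{-\beta_1}$; the Slope Index of Inequality
is the difference $\mathrm{SII} = v(0) - v(1)$ on the proportion scale.
Because these are regression-based, they use the entire wealth gradient
rather than an extreme-group contrast.  Confidence intervals use a
block-clustered sandwich covariance (see below): the trial's
randomization blocks are the independent units, and repeated
measurements per child are absorbed at that level.  The RII interval is
formed on the log scale; the SII interval by the delta method with
gradient $(v(0)-v(1),\,-v(1))$.

We deliberately compute SII from the same log-link fit as RII (as the
difference of its two endpoint predictions) rather than from a separate
identity-link fit; one fitted gradient then yields both indices and they
cannot disagree about its direction.

## Stratum effects and interaction tests

For strata defined by wealth tertile, season, or their cross, arm
contrasts come from two binomial GLMs with an arm indicator: identity
link for the prevalence difference (PD = control − intervention) and log
link for the prevalence ratio (PR).  With a saturated arm-only model
these reproduce the empirical stratum prevalences exactly, which the
test suite asserts to 1e-10; the GLM formulation matters because it
supplies the coefficient covariance for delta-method CIs.

Identity-link binomial IRLS can leave the unit interval and fail.  The
fallback is the linear-probability fit (same estimand — cell means and
their difference — and the cluster-robust covariance remains valid), and
the affected estimate is flagged `lpm-fallback`.  Log-link failures fall
back to a modified Poisson fit (log link with robust errors), flagged
`poisson-fallback`.  Strata with zero events keep a row with a
`degenerate` flag instead of disappearing.

Effect modification is tested by a Wald-type F statistic on the
interaction coefficients of the model with arm × modifier terms, using
the block-clustered covariance:
$F = \hat\theta' \widehat V_\theta^{-1} \hat\theta / q$ with $q$
interaction coefficients, referred to $F(q,\; B - p)$ where $B$ is the
number of blocks and $p$ the number of model parameters.  The
denominator df is a small-sample cluster correction: with 90 blocks it
is mildly conservative, and the suite verifies type-I error stays in
[0.03, 0.07] at nominal 0.05 over 1,000 null simulations.  With two
modifiers the tested terms are the highest-order arm × modifier-1 ×
modifier-2 coefficients — i.e. whether wealth-related modification
itself differs by season — which matches reading a joint-stratification
figure for a three-way pattern.

## Penalized-spline dose-response over wealth rank

The continuous-wealth analysis fits a generalized additive model with a
separate penalized cubic regression spline of rank per arm (shared basis
dimension, default $k = 10$), an arm main effect (intervention as the
reference level), and block-level random intercepts as a ridge-penalized
term, with all smoothing parameters chosen by REML (via mgcv).  The
Gaussian/identity fit yields each arm's prevalence curve; the PD curve
is their difference, with pointwise bands from the joint coefficient
covariance (random-effect columns zeroed so predictions are
population-level).  The PR curve uses a binomial log-link GAM; if that
likelihood fails to converge, PR is derived from the Gaussian arm curves
by the delta method and flagged `pr-from-gaussian`.

Numerical choices: basis dimension is reduced (with a warning) when the
data have fewer distinct ranks than basis functions; as the smoothing
penalty grows the cubic-regression smooth collapses to its linear null
space, and the suite checks that a very large fixed penalty yields a
straight-line PD curve; evaluation outside the fitted rank support is
clamped to the boundary with a warning, because splines extrapolate
poorly and the projection grid can reach ranks the trial barely
observed.

## Season classification from rainfall

Monsoon season is defined from daily precipitation: the trailing 5-day
rolling mean is computed, and each year's monsoon interval spans the
first to the last day on which that mean is *strictly above* 10 mm.
The trailing (right-aligned) window and the first-to-last-exceedance
rule are our choices where the verbal definition ("weeks with elevated
precipitation") is loose; a centered window is available via an
argument.  The trial's own printed windows (May 27 – Sep 27, 2014;
Apr 1 – Sep 26, 2015) ship as a built-in calendar and are the default
for trial-shaped data; interval endpoints are inclusive.  The
heavy-rainfall sensitivity indicator is 1 when any of the 7 calendar
days ending the day before the measurement exceeds the 80th percentile
of all daily totals (percentile computed once over the full series,
with R's default inclusive empirical quantile).

## Wealth index construction

Assets are screened before PCA: WASH-related variables are excluded by
name (an index used to study a WASH intervention must not contain the
intervention's own targets), columns with ≥ 10% missingness are dropped,
and near-constant columns are dropped (variance below 0.01 for
continuous assets; minority-class share below 1% for binary ones — the
floor is our quantification of "near-zero variation").  Missing
continuous values are mean-imputed; missing binary values become their
own level via a companion indicator column.  The index is the first
principal component of the correlation matrix (standardized variables —
the asset set mixes acres of land with 0/1 indicators, so covariance
PCA would be scale-dependent).  The component sign is oriented so the
electricity loading is positive (higher score = wealthier); PCA is
sign-indeterminate and household electricity is a canonical wealth
marker.

Ranks are mid-rank ECDF positions $(r - 0.5)/n$, strictly inside (0, 1)
— which keeps log-link predictions at the extremes finite — with ties
averaged; tertiles cut the rank at 1/3 and 2/3 with ties to the lower
tertile.  Tertiles are computed once on baseline compound-level scores
and joined to all of a compound's observations.  For the
maternal-education sensitivity analysis, years of education are used
directly as the score and passed through the same ranking.

## Burden projection

The projection formula per grid cell is

$$\text{cases prevented per month} = \text{children under 3}
  \times \mathrm{PD}(\text{wealth rank}) \times 4\ \text{weeks},$$

where PD is evaluated from the monsoon-restricted spline (the outcome is
a 7-day prevalence, so 4 weeks converts it to a monthly case count; the
factor is exactly 4 per the published formula, not 365/12/7).  The
children layer is population × 0.31 (share aged 0–14) × 3/14 (share of
that band under 3 under a uniform age assumption); the exact fraction
3/14 is the default and the rounded 0.21 is available as a toggle.
Cells are included iff non-urban and holding strictly more than 2
children under 3.  The wealth-rank layer is the mid-rank ECDF over
included cells (a national-scope ranking is available by passing no
mask; the restriction scope is genuinely open, so both are exposed).
Negative PD cells are retained in totals and counted in diagnostics.

District uncertainty: a district total is
$T_d = w \sum_c N_c\, x(r_c)'\beta$, linear in the spline coefficients,
so $\mathrm{SE}(T_d) = \sqrt{a_d' V a_d}$ with
$a_d = w \sum_c N_c\, x(r_c)$ — cells are treated as fully correlated
through the shared coefficients, which is the correct propagation when
the only uncertainty carried forward is the fitted curve's.  "Summing
grid-cell standard errors" is ambiguous; we chose full delta-method
propagation, verified it against a 5,000-draw parametric bootstrap of
the coefficients (agreement within 3%), and kept a naive
independent-cells mode behind a flag for sensitivity comparison (the
naive SE is never larger).  A year-round projection simply refits the
PD curve without the monsoon filter and reuses the identical path.

# The synthetic-data generator

The generator exists so every stage is testable without downloads.  Its
defaults emulate the trial's design: 90 matched blocks × 4 clusters
allocated 2:1:1 to control / combined WSH / WSH+N (the latter two pooled
as the intervention arm), 12 compounds per cluster with one index child
and 2 measurements — 8,640 observations, close to the trial's 8,440.
Latent compound wealth is drawn once per compound (N(0, 1)); binary
assets threshold `loading × latent + noise` at zero and continuous
assets are affine in the latent, which guarantees the first principal
component aligns with the latent so rank recovery is a testable claim
(the suite requires Spearman ≥ 0.9 at default noise).  Season is drawn
per observation with probability 0.473 (the trial's marginal monsoon
share) rather than by modelling visit schedules, and a calendar date
consistent with the drawn season is attached.  Diarrhea is Bernoulli
with the (arm, season, true wealth tertile) cell probability.

Default cell prevalences follow the reported strata: control monsoon
10.3% / 8.5% / 6.1% across tertiles (averaging 8.3%), control dry at
about half the monsoon level (the control group's risk roughly doubles
in monsoon), and intervention flat across tertiles at 4.6% (monsoon) and
4.0% (dry) — no wealth gradient and no seasonal surge under
intervention.  The within-cluster outcome correlation is not reported
anywhere we could find, so the generator exposes a cluster-level random
intercept that defaults to off rather than guessing a value.

What the generator does **not** emulate: visit scheduling and seasonal
enrollment patterns, outcome misclassification and courtesy bias,
within-child correlation beyond block clustering, multiple children per
compound, and any spatial structure linking trial compounds to the
raster landscape.  Passing tests therefore demonstrate that the
estimators recover known truth under the design's sampling structure —
not that real reporting artifacts are overcome.

The raster generator produces a smooth wealth surface (moving-average
smoothed white noise with a controllable correlation length), a
negative-binomial population layer, a spatially coherent urban mask
(top quantile of a second smooth surface), and a Voronoi-style district
partition — plumbing with the right invariants (shared georeference,
contiguous districts, approximate urban fraction), not a geostatistical
wealth model.

# Problem sizes and tolerances in the test suite

The suite's simulation sizes were chosen so each check is decisive at
desk scale: marginal calibration of the generator uses ≥ 20,000
observations per design cell (3-binomial-SE assertions); RII closed-form
recovery uses n = 50,000 and CI coverage 500 replicates at n = 2,000;
the interaction null calibration uses 1,000 simulations of a 90-block
design; spline recovery uses n = 100,000 against a known linear PD
curve (≥ 95% of grid points within 3 pointwise SEs); projection
uncertainty is checked against a 5,000-draw bootstrap within 3%.  Exact
identities (rank ties, mask boundaries, additivity of district totals,
RII reversal, seed determinism) are asserted without tolerance.

# Known limitations

- The identity-link binomial model is kept as the primary PD estimator
  for fidelity to standard epidemiological practice, but its fallback
  (linear probability) changes the likelihood, not the estimand; flags
  make the switch visible.
- The Wald-F denominator df (blocks − parameters) is one of several
  defensible small-sample choices; third-decimal p-values can shift
  under alternatives.
- PR spline curves from the log-binomial GAM can fail on sparse strata;
  the delta-method fallback is approximate near zero intervention
  prevalence.
- The projection treats the spline coefficient covariance as the only
  uncertainty source; raster measurement error and the trial-to-target
  transportability assumptions (consistency, positivity, no unmeasured
  effect modifiers beyond wealth/season/age/rurality) are not
  quantified.
- Rank-layer ranking scope (rural-restricted vs national) and the 3/14
  vs 0.21 multiplier are exposed toggles because the published pipeline
  does not pin them down; defaults are rural-restricted and 3/14.

# A worked run

```{r example, eval = FALSE}
res <- run_pipeline(default_config(seed = 1))
res$inequality                      # RII/SII per arm
res$effects$season                  # PD/PR by season
res$interactions                    # Wald-type F tests
res$curve                           # monsoon PD spline
res$projection$national             # cases averted per 1000 children/month
```

Every table the pipeline writes (CSV), every raster (ESRI ASCII grid)
and the JSON manifest with per-file hashes land in the run's output
directory; identical config and seed reproduce identical outputs.
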