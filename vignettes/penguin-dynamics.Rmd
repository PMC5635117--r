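---
title: "Modelling Adelie penguin colony dynamics with process and observation error"
author: "apd package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Adelie penguin colony dynamics with process and observation error}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Adelie penguin colonies are censused irregularly: most site-season
combinations have no count at all, counts may be of nests or of chicks, and
each count carries an accuracy code (1 = within about 5% of truth, up to
5 = within about 50%).  Yet management questions -- is a region declining?
how fast? -- require continuous abundance series, ideally aggregated over
management areas.  Two sources of noise must be separated to answer them:

* **observation error**: a census is an imprecise measurement of true
  abundance;
* **process error**: true abundance itself fluctuates between seasons for
  reasons no covariate captures.

If process error dominates, short stretches of increase or decrease carry
little information about the environment, and only spatially aggregated or
long series identify trends.  `apd` implements a hierarchical Bayesian
state-space model that makes this decomposition explicit, together with a
power study quantifying the trend-detection consequences.

## The model

Index sites by $s$ and seasons (split austral years, labelled by the
starting calendar year) by $y$.  Latent abundance is the number of nests
$N_{s,y}$, with $\ell_{s,y} = \log N_{s,y}$.

**Growth.** For an occupied site,
$$\ell_{s,y+1} \sim \mathrm{Normal}(\ell_{s,y} + r_{s,y},\ \sigma_p^2),
\qquad
r_{s,y} = \beta_1 + \beta_2 x^{w}_{s,y} + \beta_3 x^{s}_{s,y}
          + \varepsilon_y .$$
$\sigma_p$ is the *process error* (log scale, per season).  $\beta_1$ is
the growth rate at average sea-ice conditions; the seasonal multiplier is
$e^r$.  $\varepsilon_y \sim \mathrm{Normal}(0, \sigma_\varepsilon^2)$ is a
*year effect* shared by every site -- continent-scale good and bad years.

**Sea-ice covariates** (standardized to pooled z-scores, so
$\beta_2, \beta_3$ are effects of a one-SD change):

* $x^w$: peak winter sea-ice concentration summarized over the five
  winters $y-4 \ldots y$, a krill-recruitment surrogate.  The window
  statistic is the **maximum** by default: the biological contrast is an
  "ice drought" -- no extensive winter ice anywhere in the window -- which
  a maximum detects directly, while a mean confounds one strong winter
  with five mediocre ones.  A `mean` option is provided
  (`apd_spec(winter_stat=)`) since the choice is a modelling judgement,
  not an identity.
* $x^s$: peak summer ice four seasons earlier, the birth season of the
  cohort recruiting at age 4, when summer ice governs colony access.

Both need ice data from four seasons before the first modelled season,
which the dataset validator enforces.

**Occupancy.** Colonies go locally extinct and are re-founded.  A
constant-rate Markov switch, $z_{s,y} \in \{0,1\}$ with extinction
probability $p_{ext}$ and colonization probability $p_{col}$, keeps
zero-count seasons in the likelihood without asserting any
size-dependence of extinction risk -- a size-dependent form is not
estimable from the handful of observed extinctions, so we deliberately
use the simplest mechanism that preserves the phenomenon.  A colonization
re-founds abundance from a lognormal prior centred on a small colony
(10 nests, sdlog 1).

**Productivity.** Chick counts inform abundance through breeding
productivity $\alpha_{s,y}$ (chicks per nest), drawn hierarchically from
$\mathrm{Normal}(\mu_\alpha, \sigma_\alpha^2)$ truncated to $[0, 2]$ (a
two-egg clutch bounds productivity at 2).  The prior on $\mu_\alpha$ is
informative -- $\mathrm{Normal}(0.9, 0.3^2)$ -- because with sparse chick
data the mean and variance of productivity are otherwise unidentified.

**Observation.** A census with accuracy code $c$ has lognormal error
$$\text{nest count} \sim \mathrm{round}\,\mathrm{Lognormal}(\ell_{s,y},
  \sigma_o(c)^2), \qquad
  \text{chick count} \sim \mathrm{round}\,\mathrm{Lognormal}(\ell_{s,y} +
  \log \alpha_{s,y}, \sigma_o(c)^2),$$
with $\sigma_o(c) = \log(1 + e_c)/z_{0.975}$ for envelopes
$e = (0.05, 0.10, 0.15, 0.25, 0.50)$: code $c$ means the count is within a
multiplicative factor $(1+e_c)$ of truth with 95% probability (code 5:
$\sigma_o \approx 0.207$).  The envelope ladder is the conventional census
accuracy scale and is configurable so an alternative calibration can be
substituted verbatim.

**Priors** elsewhere are weakly informative: $\beta_j \sim
\mathrm{Normal}(0, 0.1^2)$ (seasonal log growth rates beyond $\pm 0.3$ are
implausible), half-normal(0.5) on $\sigma_p$ and $\sigma_\varepsilon$,
$\mathrm{Beta}(1, 9)$ on $p_{ext}$ and $p_{col}$, and a diffuse
$\mathrm{Normal}(\log 500, 2^2)$ on initial log abundance.

## Fitting, imputation, hindcasting

```{r}
library(apd)
sim <- simulate_dataset(scenario_presets("small"), seed = 1)
fit <- apd_fit(sim$dataset, seed = 1)
summary(fit)
predict(fit, horizon = 1)   # imputed series plus a one-season forecast
```

`apd_fit()` samples the joint posterior with JAGS; the model handed to the
sampler is the same joint density implemented independently in
`log_joint_density()`, which the test suite uses for cross-checking.
Numerical conventions worth knowing:

* **Occupancy data.** A positive count pins $z_{s,y} = 1$; a zero nest
  count pins $z_{s,y} = 0$; a zero chick count alongside a positive nest
  count is breeding failure, not absence.  Remaining indicators are
  sampled.  (An occupied colony's rounded count could in principle be 0,
  but only at abundances below one nest, irrelevant at census scales.)
* **Continuous-scale likelihood.** Observation densities are evaluated at
  the recorded count on the continuous scale -- standard for large counts
  -- with zero counts from occupied sites evaluated at 0.5, the rounding
  boundary.
* **Latent abundance everywhere.** The sampler draws $\ell_{s,y}$ for
  every modelled site-season, so unsurveyed seasons are imputed by the
  fit itself, and seasons before a site's first count are informed
  backwards through the process chain.  `hindcast()` additionally extends
  draws *before* the modelled range by inverting the growth map,
  $\ell_y = \ell_{y+1} - r_{s,y} - w$, drawing pre-range year effects from
  their prior.  `apd_forecast()` steps forward with fresh year effects and
  process noise, carrying the last season's covariates forward (future sea
  ice being unknown).
* **Initialization** is deterministic: latent $\ell$ at
  $\log(\text{count}+1)$ interpolated across gaps, parameters at prior
  centres; chain RNG seeds derive from the user seed, so a fit is a pure
  function of (dataset, spec, seed).
* **Convergence** is checked on $\beta_1..\beta_3$, $\sigma_p$,
  $\sigma_\varepsilon$, $\mu_\alpha$, $\sigma_\alpha$ and every
  $\varepsilon_y$: split R-hat $\le 1.05$ and effective sample size
  $\ge 200$ by default.  Failures warn (or error, per
  `spec$convergence$on_fail`) naming the offending scalars.

## Post-fit quantities

* `growth_multipliers()`: per draw and site, the geometric mean of
  successive abundance ratios over consecutive occupied pairs ("actual"),
  or of $e^{r_{s,y}}$ over the same pairs ("predicted").  The two coincide
  exactly at $\sigma_p = 0$; their divergence is a direct display of
  process noise.  Parameter-style summaries use equal-tailed intervals.
* `apd_aggregate()`: regional abundance summed *per draw* (additivity is
  exact draw by draw; summing site medians would not give the median of
  the sum), summarized with highest-posterior-density intervals, the
  convention used throughout for abundance-scale quantities.  The HPD is
  the narrowest window of $\lceil p \cdot n \rceil$ sorted draws.
* `finite_population_sd()`: the sample SD (n-1) of each variance source's
  realized values -- year effects, winter term, summer term, process
  residuals -- putting fixed and random sources on one scale.
* `obs_vs_process()`: the posterior fraction of counts whose
  $\sigma_o(\text{code})$ is below $\sigma_p$ -- the single number that
  says whether counting harder or counting more places is the better
  investment.
* `year_effect_correlation()`: per-draw Pearson correlation of
  $\varepsilon_y$ with any user-supplied annual index, propagating
  posterior uncertainty instead of correlating medians (the median-based
  value is also reported).
* `density_dependence()`: realized minus predicted growth against
  abundance, a diagnostic for unmodelled density dependence (the model
  itself is density-independent: carrying capacities are not estimable
  site by site).
* `posterior_predictive_counts()`: replicated counts per census record
  with HPD intervals -- the calibration check that about 90% of observed
  counts should fall in their 90% intervals.

## The trend-detection power study

`run_trend_grid()` asks: if true abundance follows exponential growth at
rate $r$ with lognormal process noise $\sigma$ (no observation error, no
occupancy dynamics -- the question is about process noise alone), how often
does a monitoring analysis of a series summed over $k$ sites recover the
*sign* of $r$ unambiguously?

The default detection rule is a two-sided t-test on the mean log-difference
of the summed series (`diff_t`).  This choice matters: the seemingly
natural OLS regression of log abundance on year is invalid under the null
here, because a driftless geometric random walk violates the independence
of regression errors -- the classic spurious-regression effect.  At 10
years and $\sigma = 0.2$ the OLS slope test calls a trend in roughly half
of all null series; the differenced t-test is exact at the nominal 5%.
The OLS rule (`ols_ci`), an endpoint comparison and a bare sign rule remain
available for comparing definitions of "unambiguous".

Default grids span seasonal multipliers 0.90-1.10, $\sigma = 0.2$, 1-50
sites and 3-20 years, 1000 replicates per cell; `plot()` draws the heat
map per $(r, \sigma)$.

## What the synthetic generator does and does not emulate

`simulate_dataset()` runs the fitted model forward: AR(1)-on-logit sea-ice
series (autocorrelation 0.3 -- smooth, bounded, site-heterogeneous; any
smooth bounded field would do, and the generator is pluggable), latent
occupancy/abundance via the model's own step functions, hierarchical
productivities, and a survey design with a configurable site-season survey
probability, nest/chick mix and accuracy-code distribution (15% in the
lowest-precision category by default).  True parameters default to the
fitted system's character: $\sigma_p = \log(1.5)/1.96 \approx 0.207$
(process noise equivalent to a +/-50% census), $\sigma_\varepsilon = 0.15$
(year effects the dominant source), a small positive winter effect and a
weakly negative summer effect, 0.9 chicks per nest.

What it does **not** emulate: real Antarctic geography, satellite-derived
ice fields and their spatial correlation across neighbouring sites, any
dependence of survey effort on abundance (surveying is independent of the
state), age structure, skipped breeding, or density dependence.  Passing
recovery and calibration tests on these data therefore demonstrates the
*internal* consistency of model, sampler and post-fit operations -- not
that the model is a complete description of real colonies.

## Calibration studies and problem sizes

The package's own checks use deliberately small configurations: parameter
recovery runs 50 refits of the 5-site x 10-season `small` preset
(expecting 90% interval coverage near 45/50); simulation-based calibration
runs 20 refits with all hyperparameters drawn from their priors, testing
rank uniformity with a coarse 4-bin chi-square; the trend study's
monotonicity checks use a 3 x 3 x 4 subgrid at 1000 replicates.  These
sizes give the properties room to fail visibly while keeping a full run of
the suite on one CPU comfortable.

## Known limitations

* No age or stage structure and no non-breeding state: process error
  absorbs skipped breeding and vital-rate variation indistinguishably.
* No density dependence; the `density_dependence()` diagnostic is the
  honest substitute.
* Extinction risk is size-independent by construction.
* One shared accuracy map for nest and chick counts.
* Forecast covariates are carried forward, so multi-season forecasts
  ignore future ice variability (year effects and process noise are
  propagated).
* The continuous-scale observation density is an approximation that
  degrades for very small counts (a few nests).
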