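# apd — Adélie penguin colony dynamics

`apd` fits a hierarchical Bayesian state-space model to sparse, irregular
census records of Adélie penguin breeding colonies and separates the two
kinds of noise that contaminate such series: **observation error** (a
census is an imprecise measurement, encoded by an accuracy code 1–5) and
**process error** (true abundance fluctuates between seasons for reasons no
covariate explains). It is aimed at seabird ecologists and managers who
need continuous, regionally aggregated abundance series from patchy
monitoring data, and who need to know how much of a short-term change is
signal.

## The model

For site *s* and season *y* (split austral years), latent log nest
abundance follows

> ℓ<sub>s,y+1</sub> ~ Normal(ℓ<sub>s,y</sub> + r<sub>s,y</sub>, σ²<sub>p</sub>),  r<sub>s,y</sub> = β₁ + β₂·x<sup>w</sup><sub>s,y</sub> + β₃·x<sup>s</sup><sub>s,y</sub> + ε<sub>y</sub>

with standardized sea-ice covariates (five-winter peak-ice statistic; lag-4
summer peak ice), a year effect ε<sub>y</sub> ~ Normal(0, σ²<sub>ε</sub>)
shared by every colony, and process error σ<sub>p</sub>. Site occupancy is
a constant-rate extinction/colonization switch (zero nest counts are data,
not gaps). Nest and chick counts are rounded lognormal observations of
N<sub>s,y</sub> and α<sub>s,y</sub>·N<sub>s,y</sub>, where productivity
α (chicks per nest) is hierarchical truncated-normal on [0, 2], and the
observation scale σ<sub>o</sub>(code) = log(1 + e)/1.96 comes from 95%
multiplicative envelopes e = (5, 10, 15, 25, 50)%. Latent abundance is
sampled for every modelled site-season, so missing seasons are imputed and
early seasons hindcast as part of the fit. A companion simulation study
(`run_trend_grid()`) quantifies how often the *sign* of a true growth rate
is recovered from noisy series as a function of series length and the
number of sites aggregated.

The full model, priors, and numerical conventions are in the vignette
(`vignettes/penguin-dynamics.Rmd`).

## Worked example

Simulate a small campaign from known parameters and refit it:

```r
library(apd)
sim <- simulate_dataset(scenario_presets("small"), seed = 1)
sim$dataset
#> Adelie census dataset
#>   sites:   5 (1 region(s))
#>   seasons: 1982..1991
#>   counts:  44 records (33 nest, 11 chick; 0 zero counts)

fit <- apd_fit(sim$dataset, seed = 1)
summary(fit)
#>      parameter    2.5%     25%     50%     75%  97.5%   rhat       ess
#>          beta1 -0.0735  0.0067  0.0450  0.0789 0.1495 0.9998 1461.5581
#>          beta2 -0.0589  0.0014  0.0334  0.0660 0.1258 1.0013 1515.8407
#>          beta3 -0.1438 -0.0766 -0.0423 -0.0114 0.0566 1.0004 1768.7018
#>  sigma_process  0.1760  0.2166  0.2442  0.2738 0.3474 1.0035  746.5733
#>      sigma_eps  0.0157  0.0983  0.1507  0.2074 0.3596 1.0137  438.1900
#>       mu_alpha  0.7105  0.8775  0.9505  1.0185 1.1733 1.0033  861.8825
#>    sigma_alpha  0.2151  0.2901  0.3410  0.4078 0.6171 1.0047  746.7260
#>          p_col  0.0025  0.0312  0.0735  0.1386 0.3413     NA        NA
#>          p_ext  0.0004  0.0051  0.0117  0.0239 0.0661     NA        NA
```

The generating values (β₁ = 0.02, β₂ = 0.03, β₃ = −0.01,
σ<sub>p</sub> = 0.207, σ<sub>ε</sub> = 0.15) all sit inside their 95%
intervals; the columns are posterior quantiles plus split R-hat and
effective sample size for each monitored scalar.

```r
obs_vs_process(fit)
#> Counts with observation error below process error: 100% (95% CI: 91%, 100%) of 44 counts
```

Here even the least precise census code carries less noise than one
season of process error — the posterior for σ<sub>p</sub> sits above
σ<sub>o</sub>(code 5) ≈ 0.207 — so for these (synthetic) colonies,
surveying *more sites* beats counting any one site more carefully.

```r
growth_multipliers(fit, "actual")$summary$median
#> [1] 1.019 1.167 1.133 1.039 0.965
```

These are per-site geometric-mean seasonal multipliers of abundance over
occupied season pairs (1.0 = stable). Other post-fit tools:
`predict(fit, horizon = 1)` (imputed series plus a forecast),
`apd_aggregate()` (regional sums per posterior draw, 90% HPD),
`finite_population_sd()` (variance partitioning of the growth rate),
`hindcast()`, `posterior_predictive_counts()`, `density_dependence()`,
`year_effect_correlation()`.

A thin command-line front end covers the same pipeline from the shell
(`simulate-data`, `fit`, `aggregate`, `report`, `simulate-trend`); see
`?apd_cli`.

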