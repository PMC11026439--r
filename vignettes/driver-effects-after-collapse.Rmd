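---
title: "Driver effects on biomass change before and after a stock collapse: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver effects on biomass change before and after a stock collapse: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collapseshift)
```

## The question and the model

Fish stocks that collapse and later rebuild their biomass may not come back
as the same dynamical system: the sensitivity of biomass change to fishing
pressure, sea temperature and recruitment can shift. `collapseshift`
quantifies that shift with a deliberately simple, comparable-across-stocks
model. For one stock and one period (before or after the collapse),

$$\Delta \ln(B)_{yr-1 \to yr} = a + b\,zF_{yr-1} + c\,zST_{yr-1}
  + d\,zRec_{yr} + \varepsilon_{yr}, \qquad
  \varepsilon_{yr} \sim \mathcal{N}(0, \sigma),$$

with $B$ total biomass (Mt), $F$ fishing mortality (1/year, lagged one
year), $ST$ regional annual sea temperature (°C, lagged one year), and
$Rec$ recruitment (numbers, same year). Working on the log-ratio response
absorbs much of the serial dependence of a biomass series, so no year term
is used; the remaining error is assumed independent Gaussian.
Covariates are standardized to z-scores *within each period's window*, so
$b$, $c$, $d$ are on a common per-standard-deviation scale and can be
compared across periods, stocks and drivers. The two periods are fit
independently: the working hypothesis is precisely that the parameters may
differ, so nothing is shared.

Assumptions worth keeping in view: linearity of the standardized-driver
effects, homoscedastic Gaussian noise, no interactions (temperature ×
recruitment is ecologically plausible but costs data the windows do not
have), and drivers measured without error.

## Collapse qualification

A stock enters the analysis only if its biomass describes a V shape around
the global minimum. The named criteria, applied in order and all reported:

* **LENGTH** — at least 30 years of biomass data.
* **COVARIATES** — fishing mortality, temperature and recruitment present
  on every year the minimal windows need (gaps are not interpolated: the
  response needs adjacent years, so a gap is a missing-covariate failure).
* **SIDES** — at least 15 years of data strictly before and strictly after
  the minimum year (ties for the minimum break to the earliest year).
* **RECOVERY_BEFORE / RECOVERY_AFTER** — within the 15 years on each side
  of the minimum, at least one biomass value at or above 30% of the
  whole-series maximum. The threshold is relative, so the verdict is
  invariant to rescaling biomass.

The 30% screen is applied within 15-year windows adjacent to the minimum
(the modelling windows may extend to 20 transitions); whether the original
screen used 15 or 20 years is ambiguous, so the window is a parameter
(`recovery_window`). The minimum year anchors both modelling windows: the
transition *into* the minimum year belongs to "before", transitions *out of*
it to "after" — this keeps the two slices disjoint in transitions while
using all data; the alternative (dropping the minimum-year transition) was
rejected because the windows are short already. Each slice takes as many
transitions as available up to 20 and requires at least 15.

## Priors, sampler, and diagnostics

The reference protocol fits by MCMC with weakly informative priors on the
data's scale (the applied-regression default convention): intercept
$\mathcal{N}(\bar y,\, 2.5\,s_y)$, slopes $\mathcal{N}(0,\, 2.5\,s_y /
s_{x_j})$ (with $s_{x_j} = 1$ after z-scoring), and
$\sigma \sim \text{Exponential}(1/s_y)$. No Hamiltonian Monte Carlo backend
is assumed: because the likelihood is Gaussian and the coefficient prior
normal, the coefficient vector has an exact multivariate-normal full
conditional, and $\log\sigma$ is drawn by slice sampling (Neal's
stepping-out procedure, width 0.5, cap 50 steps). Every retained draw
therefore targets the stated posterior exactly, and the whole chain is
reproducible from an integer seed. The `target_accept` field of
`mcmc_config()` is recorded for interface fidelity with HMC backends but is
inert here.

Iteration accounting follows the reference protocol: 4 chains × 10,000
iterations, first half warmup, thinning 10 → 500 retained draws per chain,
2,000 total. Two diagnostics gate retention:

* **Split-R̂** (`compute_rhat()`): each chain halved; with $W$ the mean
  within-half variance and $B$ the between-half-mean variance times the
  half-length $n$, $\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$. Chains that have
  not mixed give $\hat R > 1$; $W = 0$ with spread gives `Inf` (reported,
  never an error); fully constant identical chains give `NaN`. The
  retention rule demands $\hat R \le 1.01$ for every parameter in both
  period fits.
* **Median Bayesian R²** (`bayes_r2()`): per draw,
  $R^2_s = V_s/(V_s + \sigma_s^2)$ with $V_s$ the sample variance of the
  linear predictor over rows; the median over draws must reach 0.2 in both
  periods.

A practical note discovered while testing: with few retained draws per
chain (e.g. 100, as in heavily reduced desk profiles), split-R̂ of
*perfectly mixed* draws fluctuates above 1.01 for a substantial fraction of
fits — the threshold is strict relative to the diagnostic's own sampling
noise. Reduced profiles in the analysis drivers therefore run unthinned
(the Gibbs draws carry almost no autocorrelation, so thinning only starves
the diagnostic); the full protocol keeps the reference thinning.

Degenerate inputs are errors where the quantity is undefined (constant
response; a covariate constant within a window, whose z-score does not
exist; non-positive biomass, whose log does not exist) and diagnostics
where the model can speak (non-convergence excludes a stock, it never
aborts the run).

## Comparing periods

For each retained stock and each of $b$, $c$, $d$ (optionally $a$):

* **Exceedance probability** — resample 10,000 values with replacement
  independently from each period's retained draws;
  $p = \Pr(\text{after} > \text{before})$ with ties counting as "not
  greater". Flags mark $\ge 80\%$ or $\ge 90\%$ of the resampled mass on
  either side ($p \ge 0.9$ or $p \le 0.1$ for the 90% flag), so the 90%
  flag implies the 80% one. Plain pairing of the retained draws would
  estimate the same functional; resampling is kept for fidelity to the
  described procedure.
* **Six-area classification** — the (before, after) plane off the axes and
  diagonal partitions into: positive stronger ($0 < b_{\text{bef}} <
  b_{\text{aft}}$), positive weaker, negative stronger, negative weaker,
  positive→negative, negative→positive. The point estimate is the
  posterior median (configurable to the mean; the source convention is not
  stated). Exact zeros or ties are measure-zero for continuous posteriors;
  they are nudged toward the sign of (before + after) so the partition
  stays exhaustive, and flagged as boundary cases.
* **Change of effect** — `after − before`; positive values mean the effect
  moved toward more positive. Grouped summaries report n, median, Q1/Q3
  and the 5th/95th percentiles per habitat or per life-history tertile
  (type-7 linear-interpolation quantiles, stated in the output; tertile
  edges are logged because the original life-history bin boundaries are
  not published).

## What the synthetic cohort emulates — and what it does not

The generator inverts the analysis model exactly: it draws covariates
(fishing mortality as a linear ramp to a peak at the collapse year then a
step down to a managed level, with multiplicative lognormal jitter;
temperature as a stationary AR(1); recruitment i.i.d. lognormal, optionally
correlated with the previous year's temperature to induce collinearity for
VIF checks), z-scores them within the same windows the analysis will use,
and accumulates $\ln B$ with the period's parameters and stored Gaussian
noise. Stored truth makes three kinds of test possible: exact
reconstruction of every increment, parameter recovery on the estimation
scale, and truth-table agreement for the selector.

Design choices a user should know:

* **Default noise** σ = 0.15 is a configuration choice with no claim of
  realism; assessment time series do not come with a published process-σ.
* **Conditioning on the truth table.** A 40-step random walk at σ = 0.15
  wanders by factors of e±1; a single unconditioned draw can contradict the
  intended verdict. `simulate_cohort()` therefore redraws a stock's noise
  seed (bounded attempts) until the realized path matches its intended
  archetype. The cohort is a *conditional* sample — that is what makes its
  truth table true — and coverage-style experiments avoid the conditioning
  by calling `simulate_stock()` directly.
* **Slope-aware recovery rate.** Because the fishing effect acts on a
  monotone z-scored ramp, the pre-collapse path bulges above its start by
  an amount depending on the fishing coefficient; the generator sets the
  post-collapse drift from the noise-free skeleton so the recovery clears
  the 30% screen while the series maximum stays pre-collapse for typical
  draws.
* **Non-qualifying archetypes** violate one named criterion each: a
  25-year series (LENGTH — necessarily also SIDES, which no sub-31-year
  series can satisfy), decline-then-flat-low (RECOVERY_AFTER with an
  interior minimum; a strictly monotone decline would instead fail SIDES,
  its minimum being the last year), and a long slow decline whose high
  biomass predates the 15-year window (RECOVERY_BEFORE).
* **The gridded temperature field** is a stand-in for a reconstruction
  product: by default every cell and month carries the year's value, so
  the regional yearly average recovers the annual series exactly;
  `annual_means` can embed a stock's exact series for route-equivalence
  tests. Cell inclusion is by cell-center-in-box, unweighted.

What a green test does **not** establish: realism of effect sizes or noise
levels for any actual stock; behaviour under age structure, density
dependence, regime-dependent observation error, or spatially structured
temperature — none of which the generator produces; and robustness of the
selector's anchoring, which deserves its own caveat:

* **Window anchoring is approximate.** The generator switches regimes at a
  fixed collapse year, but the analysis anchors windows at the *realized*
  biomass minimum, which can sit one or more years away (the lagged
  peak-fishing year is an extreme-leverage covariate in the first
  post-collapse transition and can push the realized minimum past the
  switch; a positive pre-collapse fishing coefficient turns the ramp into
  growth and pulls it earlier). Classification-fidelity experiments
  therefore anchor windows at the true collapse year — they measure the
  fit-and-classify machinery, while selector agreement is tested
  separately against the truth table. On real data the analogous statement
  is that "before" and "after" are defined by the observed minimum, not by
  the (unknowable) dynamical switch point.

## Numerical conventions

Sample standard deviations use denominator $n-1$ everywhere (recorded in
`raw_stats`, so either convention is reproducible). Minimum ties break to
the earliest year. Quantiles are type 7. Exactly-zero posterior medians
count as positive in sign-ratio tables (measure-zero in practice,
conserving counts). The run report serializes with stable key order and
full precision so reruns with identical seeds are byte-identical. Every
random quantity — covariate draws, noise, chain starts, resampling —
derives from explicit integer seeds.

## Known limitations

The model is a single shared linear form; stocks with strongly nonlinear
driver responses will fit poorly and be excluded by the R² filter rather
than modelled. Temperature enters as a coarse regional annual mean, a weak
proxy for what a demersal stock experiences. Recruitment enters in raw
numbers by default (the source scale); a log-recruitment switch exists
because the choice is not documented. The retention threshold R̂ ≤ 1.01 is
strict relative to diagnostic noise at small retained-draw counts (see
above). Finally, the comparison treats the two period posteriors as
independent, which is exact under independent fits but ignores that both
derive from one stock's history.
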