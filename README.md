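# collapseshift

Does a fish stock respond to its drivers the same way after a biomass
collapse as it did before? `collapseshift` implements an analysis pipeline
for that question: it screens annual stock-assessment time series for
collapse-and-recovery trajectories, fits a Bayesian linear regression of the
annual log-biomass change on standardized drivers independently in the
periods before and after the biomass minimum, and quantifies how each
driver's effect changed.

The package is aimed at fisheries and quantitative-ecology analysts working
with stock-assessment style data (annual total biomass in Mt, instantaneous
fishing mortality in 1/year, recruitment in numbers, plus a gridded monthly
sea-temperature product). Because real assessment databases are large,
versioned and external, the package ships a first-class synthetic-cohort
generator with exactly the statistical structure the regression assumes, so
every stage can be exercised and tested against known ground truth.

## The model

For each stock and each period (before/after the collapse), annual biomass
change is modelled as

    Δln(B)_{yr-1→yr} = a + b·zF_{yr-1} + c·zST_{yr-1} + d·zRec_{yr} + ε_yr,
    ε_yr ~ Normal(0, σ)

where `F` is fishing mortality, `ST` regional annual sea temperature, `Rec`
recruitment, each standardized to z-scores within the period's window so
that `b`, `c`, `d` are directly comparable effect sizes. A stock qualifies
for analysis when its biomass describes a V shape: at least 30 years of
data, at least 15 years on each side of the biomass minimum, and at least
one biomass value of ≥ 30% of the series maximum within the 15 years on
each side (a ≥ 70% collapse followed by recovery). Models are fit by MCMC
(four chains, 10,000 iterations, thin 10 in the reference protocol) under
weakly informative priors; stocks are retained when both period fits reach
median Bayesian R² ≥ 0.2 and split-R̂ ≤ 1.01. Retained before/after
posteriors are compared by resampling them independently 10,000 times
(exceedance probabilities with 80%/90% credibility flags), classified into
six effect-change areas (positive/negative effect becoming
stronger/weaker/switching sign), and aggregated by habitat and by
life-history tertiles (von Bertalanffy K, common length, longevity).

## Worked example

The `analysis/` directory holds the numbered drivers of the full study on a
synthetic 30-stock cohort (half qualifying, half violating one named
selection criterion each):

```sh
Rscript analysis/01_simulate.R   # cohort + gridded SST field -> results/
Rscript analysis/02_select.R    # collapse screen vs. generator truth
Rscript analysis/03_fit.R       # before/after Bayesian fits + retention
Rscript analysis/04_compare.R   # exceedance probabilities, six areas
Rscript analysis/05_report.R    # habitat/life-history summaries, run report
```

A run prints, among other things:

```
selected 15 of 30 stocks; verdicts agree with truth for 30/30
fitted 15 stocks; retained 14 (median R2 >= 0.2 both periods, all Rhat <= 1.01)
sign ratios (negative/positive) per driver and period:
 parameter period ratio
         b before  14/0
         b  after   7/7
         c before   8/6
         c  after   6/8
         d before  0/14
         d  after  2/12
```

Read: every selection verdict matched the generator's truth table; before
the collapse all 14 retained stocks had a negative fishing effect (ratio
14/0), after it only half did (7/7) — the simulated cohort was built with a
weakening fishing effect, and the pipeline recovers that. Temperature
effects stay mixed and recruitment effects stay mostly positive, with the
per-stock detail in `results/comparison.csv` (exceedance probabilities and
six-area classes) and the habitat/life-history box-plot statistics in
`results/group_summary_*.csv`.

In code, the same path for a single stock:

```r
library(collapseshift)
coh <- simulate_cohort(10, qualifying_fraction = 1, seed = 1)
st  <- coh$stocks[[1]]
cw  <- check_collapse(st)             # qualifies, min year, threshold
sl  <- split_periods(st, cw)
fb  <- fit_period_model(build_dataset(sl$before), mcmc_config(seed = 2))
fa  <- fit_period_model(build_dataset(sl$after),  mcmc_config(seed = 3))
compare_posteriors(fb, fa, seed = 4)  # P(after > before) per parameter
classify_change(median(fb$draws[, "b"]), median(fa$draws[, "b"]))
```

## Acceptance script

`scripts/acceptance.R` re-runs the entire pipeline from scratch — simulating
a cohort, screening it, fitting both period models per stock, applying the
retention filter and aggregating — under a caller-supplied seed, and writes
the computed target values as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It also leaves the full machine-readable run report next to the output as
`run_report.json`.
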