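# condcorr

Conductance correlations and activity type in model neuron databases.

## What this package is for

Identified neurons — the classic cases come from the crustacean
stomatogastric ganglion (STG) — produce remarkably reliable electrical
activity despite severalfold animal-to-animal variability in their
ion-channel maximal conductances. Experiments show that several STG cell
types instead maintain cell-type-specific *linear correlations* between
pairs of conductances, suggesting that regulating conductance ratios helps
define cellular identity. `condcorr` provides the complete computational
counterpart of that idea for people who study parameter spaces of
conductance-based models:

1. **Simulate** a grid database of single-compartment model neurons — eight
   currents (Na, CaT, CaS, A, KCa, Kd, H, leak), first-order gating, an
   intracellular calcium pool with a dynamic Nernst reversal — each maximal
   conductance varied over equidistant levels (the shipped grid is 6 levels
   × 8 conductances = 6⁸ = 1,679,616 models). Kinetics are a versioned YAML
   configuration, not hard code.
2. **Classify** every model's intrinsic activity into silent, periodic /
   irregular spiking, periodic / irregular bursting, or one-spike bursting,
   with all the scalar descriptors: spike frequency, burst period and
   duration, duty cycle, slow-wave peak and amplitude, and the rise-phase
   slopes of the slow wave.
3. **Partition** the database into activity-defined sub-populations
   (single-metric bins and multi-criteria "pacemaker" conjunctions).
4. **Screen** each population's 28 conductance pairs for linear dependence:
   a pair is a correlation when the *raw* chi-squared statistic of
   independence exceeds 500 **and** the Spearman rank correlation (midranks
   for ties) satisfies |ρ| > 0.2, both strictly:

   χ² = Σᵢⱼ (Oᵢⱼ − Eᵢⱼ)² / Eᵢⱼ,  Eᵢⱼ = rᵢcⱼ/N.

   The statistic is used raw — no p-value, no scaling by N — so that
   sparsely populated activity types need proportionally stronger patterns
   to pass. Independence and difference matrices and an edge-concentration
   review flag support inspection of each hit.
5. **Impose** discovered correlations back on the whole database:
   threshold the correlation's histogram at 3% of the source population
   per cell to form a mask, select every model (of any activity) inside the
   mask(s), and measure enrichment of the source activity type via

   f_Success = [N(cb∩typeᵢ)/N(cb)] / [N(O∩typeᵢ)/N(O)],

   with matched random-mask and ideal-diagonal-band controls.

A synthetic-data module generates everything the tests need without
external data: analytic voltage-trace fixtures with exactly known metrics,
and surrogate databases with planted diagonal-band dependencies of chosen
sign, width and adherence.

## Worked example

Plant a positive CaS/KCa band in the bursters of a 20,000-model surrogate
database, recover it with the screen, and measure the enrichment its mask
produces:

```r
library(condcorr)

pl <- data.frame(type = "burster", cond_a = "CaS", cond_b = "KCa",
                 sign = 1, width = 1, adherence = 0.8)
db   <- make_planted_db(20000, planted = pl, seed = 1)
popb <- db[db$activity_class == "burster", ]

scan <- scan_correlations(popb, population = "burster")
scan[scan$is_correlation, c("cond_a", "cond_b", "n", "chi2", "rho", "slope_sign")]
#> # A tibble: 1 × 6
#>   cond_a cond_b     n   chi2   rho slope_sign
#>   <chr>  <chr>  <int>  <dbl> <dbl> <chr>
#> 1 CaS    KCa     6021 19196. 0.807 +
```

Exactly the planted pair passes both criteria (χ² = 19,196 ≫ 500,
ρ = 0.81 > 0.2) with the planted sign; the other 27 pairs do not. Now build
its 3% mask and select the correlation-based population:

```r
mask <- correlation_mask(popb, c("CaS", "KCa"))
cb   <- select_cb_population(db, mask)
success_report(db, cb, "burster")
#> # A tibble: 1 × 7
#>    n_db  n_cb n_type_db n_type_cb pct_success_cb pct_success_original f_success
#> 1 20000  7352      6021      5010           68.1                 30.1      2.26
```

Bursters make up 30.1% of the database but 68.1% of the 7,352 models that
obey the correlation — imposing the mask raises the odds of the target
activity 2.26-fold, the core enrichment readout.

The simulator side works the same way for real model neurons:

```r
kin <- read_kinetics()          # shipped STG kinetics + grid
g   <- c(Na = 300, CaT = 5, CaS = 4, A = 20, KCa = 15, Kd = 50,
         H = 0.01, leak = 0.01)
classify_trace(simulate_neuron(g, kin))[
  , c("activity_class", "burst_period", "duty_cycle")]
#> # A tibble: 1 × 3
#>   activity_class    burst_period duty_cycle
#> 1 periodic_bursting         600.     0.0222
```

`run_grid()` / `make_reduced_grid_db()` scale this to whole (optionally
checkpointed) grid databases; `build_populations()` enumerates the 47
activity sub-populations of the reference scheme set;
`autoplot()` methods and `plot_difference_matrix()` draw the standard
histogram, difference-matrix and scan views.

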