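---
title: "Mining conductance correlations in model neuron databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining conductance correlations in model neuron databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condcorr)
```

## The scientific question

Identified neurons — the classic examples come from the crustacean
stomatogastric ganglion (STG) — produce highly reliable electrical activity
even though the underlying ion-channel maximal conductances vary severalfold
between animals. One proposed explanation is that cells do not regulate each
conductance independently but maintain *ratios*: experimentally, several STG
cell types show cell-type-specific positive linear correlations between pairs
of conductances (the transient potassium current I~A~ and the
hyperpolarisation-activated current I~h~ being the best-known pair).

`condcorr` implements a database approach to this question. A
single-compartment conductance-based model with eight maximal conductances is
simulated on a full Cartesian grid of conductance values; each model is
classified by its intrinsic activity; activity-defined sub-populations are
screened for pairwise linear dependencies; and finally the discovered
correlations are *imposed* on the whole database to measure whether obeying a
correlation enriches the activity type it came from.

## The model and its kinetics configuration

Each ionic current is $I = \bar g\, m^p h^q (V - E)$ with first-order gating,
$\dot x = (x_\infty(V) - x)/\tau_x(V)$, an intracellular calcium pool driving
the Nernst reversal of the two calcium currents and the calcium-dependence of
the K~Ca~ current. The kinetics are *data*, not code: a versioned YAML file
defines, for all eight channels, the functional form and parameters of each
steady-state and time-constant curve, together with the membrane constants,
calcium-pool parameters and the conductance grid. The shipped default
transcribes the published STG model-database kinetics (Prinz, Billimoria &
Marder 2003, *J Neurophysiol*; kinetics lineage Liu et al. 1998 and Huguenard
& McCormick 1992) and is labelled `status: transcribed` — the values are
copied from those published tables, not fitted here, and any re-derivation
should be checked against that source. Databases record the kinetics name and
schema version in their provenance block, so a database can always be traced
to the kinetics that built it.

Numerical safeguards: gating curves are evaluated with the voltage clamped to
the configured table range (−120 to +60 mV) so extreme parameter sets cannot
overflow the exponentials, and the calcium concentration is floored at a
negligible positive value so the Nernst reversal stays defined.

## Integration choices

The integrator is exponential Euler — the de facto scheme for this model
family — applied to the gates, the membrane equation and the calcium pool in
turn; it is exact on the passive membrane, which the test suite exploits as a
closed-form oracle. Defaults: `dt = 0.05` ms, 10 s of simulated time with the
first 4 s discarded (the slowest bursters need several seconds of transient,
and periodicity tests need many cycles), initial voltage −50 mV with gating at
steady state and calcium at rest. All of these are configuration choices, not
fixed constants; halving `dt` moves classified metrics of test parameter sets
by well under 1%. Grid runs are embarrassingly parallel by record and
deterministic per record; a TSV checkpoint makes long runs resumable, and a
resumed run is verified to reproduce the uninterrupted one exactly.

## The activity taxonomy

A trace is classified into exactly one of: *silent*, *periodic spiking*,
*irregular spiking*, *periodic bursting*, *irregular bursting*, *one-spike
bursting*. The reference thresholds are immutable defaults of
`classifier_config()`:

* any strict voltage maximum above −30 mV is a spike (strict inequality;
  everything else is sub-threshold slow-wave activity);
* a train is periodic when every inter-event interval is within 1% of the
  mean interval (inclusive);
* an inter-spike interval is an inter-burst interval when it is within 30%
  of the largest ISI of the trace (inclusive, ISI ≥ 0.7·max ISI); bursts are
  the maximal spike runs between such intervals.

Several decisions are not forced by those rules and are made here
explicitly:

* **Burster periodicity.** The 1% rule is stated for spike maxima; we apply
  its mirror image to burst-start times to separate periodic from irregular
  bursters — the least surprising extension.
* **Single interval scale.** If *every* ISI qualifies as inter-burst the
  trace has one interval scale. We call it tonic spiking, *unless*
  sub-threshold slow-wave maxima sit between the spikes, in which case each
  spike is its own burst (one-spike bursting). Without this rule every tonic
  spiker would be a one-spike burster.
* **Irregular spiking vs irregular bursting.** The taxonomy's source does
  not define the boundary; here a trace is bursting exactly when *some* ISI
  fails the inter-burst test (so there are two interval scales). The maximum
  ISI is taken per-trace, not windowed.
* **One-spike bursts** have duration 0 and duty cycle 0 by the definition
  `duty = mean duration / mean period`.
* **Burst duration** is first-spike to last-spike time — the standard
  convention.
* **Sub-threshold oscillators** (maxima but no spikes) are reported silent,
  with the sub-threshold maximum count retained in `n_maxima`; degenerate
  traces (a single spike, a single burst) keep their class but are marked
  `quality = "low_event"` rather than dropped.

Burst shape metrics follow the five-point rise-phase construction: point 1 is
the inter-burst voltage minimum, point 5 the next upward crossing of the
spike threshold (linearly interpolated between samples), and points 2–4 divide
that span into four equal sections. The average slope runs 1→4 (section 4→5
is omitted to avoid the first spike's upstroke), the initial slope 1→2, the
central slope 2→4. The slow-wave peak is approximated by the last maximum in
a burst; its amplitude is peak minus the following between-burst minimum.

## Partition schemes and the 47 sub-populations

Metric bins are left-closed and right-open with open outer bins, so a model
exactly on an edge falls in the upper bin. The shipped scheme set
(`default_schemes()`) uses spike-frequency edges {10, 25, 50, 75} Hz and
duty-cycle edges {0.05, 0.1, 0.2, 0.4, 0.6}; the three rise-phase-slope
schemes (average, initial, central) each get four edges chosen from the
shape of simulated slope distributions — their sources chose such boundaries
by eye and report robustness to shifting them. Spike-height and
spikes-per-burst schemes are implemented but disabled by default (they yield
fewer correlations).

The full screened enumeration is reconstructed as: 6 tier-2 activity classes
+ 5 spike-frequency bins + 6 duty-cycle bins + 3 × 5 slope bins + 15
pacemaker-criteria populations (each of the five criteria alone plus every
pairwise conjunction) = **47 sub-populations**. The itemisation beyond the
stated class/frequency/duty-cycle schemes is a documented reconstruction,
not a printed list; `build_populations()` keeps empty populations in the
enumeration so the count is stable across databases. Pacemaker criteria are
closed ranges combined by conjunction; only the slow-wave-amplitude range
(10–30 mV) is fixed by the analysis itself — the other ranges in the config
are transcribed approximations of published STG pacemaker-kernel criteria
and are expected to be edited for other systems.

## The correlation screen

For every population and each of the 28 conductance pairs the screen
computes, on the 2-D grid histogram (other six conductances marginalised):

* the **raw** chi-squared statistic of independence,
  $\chi^2 = \sum (O-E)^2/E$ with $E_{ij} = r_i c_j / N$, cells with a zero
  row or column marginal dropped (their expectation is undefined; dropping
  is the contingency-table convention). No p-value and no scaling by $N$:
  the raw statistic grows with the number of models, which is deliberate —
  at a fixed cutoff, sparsely populated activity types must show a
  proportionally stronger pattern before they pass;
* the **Spearman rank correlation** with midranks for ties (ties dominate on
  a 6-level grid). It is computed on level indices; because Spearman
  correlation is invariant under strictly monotone relabelling, this equals
  the correlation of the conductance values themselves.

A pair is a correlation when both criteria hold *strictly*: χ² > 500 and
|ρ| > 0.2; the slope sign is the sign of ρ. An undefined ρ (constant
conductance within the population) never passes. Populations below a
configurable size floor are screened anyway with a machine-readable low-N
warning.

The complementary *independence matrix* (outer product of the normalised 1-D
marginals, scaled to counts) and *difference matrix* (observed minus
expected, percent of population per cell) support visual inspection: a true
linear dependence shows as a diagonal band in the difference matrix, while
"ramp"-type histograms vanish. The source analysis excluded statistical
passes without visible linearity by manual inspection; automating a
subjective judgement silently would be opaque, so this package instead
attaches a transparent *edge-concentration flag* (a configurable fraction of
the population in the zero-conductance row/column) to every result and
reports flagged correlations separately, never excluding them.

## Correlation-based populations and enrichment

The shape of an observed correlation is captured by thresholding its raw
histogram at 3% of the source population per cell (inclusive — "a threshold
of 3%" is read as the minimum qualifying value). The whole database,
ignoring activity type, is then filtered to the models inside every mask
(conjunction across masks — the reading consistent with combined
correlations producing stronger enrichment). Enrichment is summarised by

$$f_{\mathrm{Success}} =
\frac{N(cb_i \cap type_i)/N(cb_i)}{N(O \cap type_i)/N(O)},$$

the multiplicative change in the prevalence of the target type. Controls:
random masks on random pairs with the *cell count matched* to the
correlation mask being controlled for (the minimal fair control; whether
the original control matched cell count or mass is not stated, so the
choice is recorded in every mask), and ideal diagonal-band masks applied to
random pairs. On a database whose conductances are independent of the
activity label both controls average to $f = 1$; the full-grid mask gives
$f = 1$ identically.

```{r enrichment-example}
pl <- data.frame(type = "burster", cond_a = "CaS", cond_b = "KCa",
                 sign = 1, width = 1, adherence = 0.8)
db <- make_planted_db(20000, planted = pl, seed = 1)
popb <- db[db$activity_class == "burster", ]
mask <- correlation_mask(popb, c("CaS", "KCa"))
cb <- select_cb_population(db, mask)
success_report(db, cb, "burster")
```

## What the synthetic generators emulate — and what they do not

Two generator families make the pipeline testable without any external
data.

**Analytic trace fixtures** (`make_trace()`) are piecewise-linear waveforms
— not ODE output — with spike apexes and inter-burst minima snapped to the
sampling grid, so every classifier quantity has a known constructed value
and recovery is exact up to one sample interval. They deliberately separate
classifier correctness from integrator behaviour; ODE-based end-to-end
checks use reduced simulated grids instead. The fixtures do not reproduce
real spike shapes, afterhyperpolarisations, spike-height gradients within
bursts, or chaotic traces, so passing them demonstrates metric arithmetic,
not robustness to every waveform the simulator can produce.

**Planted databases** (`make_planted_db()`) draw uniform independent grid
levels and overwrite planted pairs, within one activity type, with cells
from a diagonal band of chosen sign, width and adherence probability — the
minimal generator of the near-linear band structure the screen is designed
to detect. The calibrated recovery operating point (band width 1, adherence
0.8, 50,000 models, 40 seeds) was fixed once by a calibration sweep; at it,
the planted pair is recovered with the correct sign, and no unplanted pair
passes, in effectively every seed. Planted databases do not emulate the
real database's class proportions, its non-uniform per-class conductance
marginals, or multi-pair interactions, so recovery there does not bound the
false-negative rate on simulated databases.

Problem sizes in the shipped tests and acceptance run: 100 trace fixtures
across the six classes; 1,000 random histograms/populations for the
statistic oracles; 40 × 50,000-model planted databases for miner recovery;
one 50,000-model label-independent database with 200 random-mask seeds and
50 ideal-band masks for the enrichment nulls. These sizes make the checks
statistically meaningful while keeping a full verification run in the
minutes range on one core.

## Reproducibility and limitations

Every stochastic stage takes an explicit seed, restores the caller's RNG
state, and embeds its generating specification in the output's provenance
attributes; `run_config()` + `config_hash()` stamp report directories.
Simulation is deterministic per record and invariant to chunking.

Known limitations, inherited from the design: the screen examines 2-D
projections of an 8-dimensional space, so dependencies involving three or
more conductances may be invisible or may smear across several pairs; the
grid is a coarse binning, and bin structure itself can create or destroy
apparent correlations; the activity taxonomy ignores responses to injected
current and neuromodulation, so classes describe *intrinsic* activity only;
and the edge-concentration flag is a heuristic stand-in for a human
judgement of linearity, intended to direct review rather than decide it.
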