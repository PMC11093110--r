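---
title: "Methods: respirometry, gill morphometry and allometric scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respirometry, gill morphometry and allometric scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gillscale)
library(dplyr)
```

## The scientific question

The gill-oxygen-limitation (GOL) hypothesis proposes that growth of fishes
and other water-breathing ectotherms is capped by geometry: gills are a
quasi-two-dimensional exchange surface supplying a three-dimensional body,
so gill surface area (GSA) supposedly cannot scale with body mass as fast
as metabolic demand. If true, this would explain the temperature-size rule
(warmer-reared ectotherms mature at smaller sizes). The hypothesis makes
testable predictions about allometric slopes, i.e. the exponents *b* of
power laws *y = aM^b* relating a trait *y* to body mass *M*:

* **Scenario 1** — GSA cannot reach *b* = 1, and metabolic rate is dragged
  down to the same exponent: *b*~MR~ ≈ *b*~GSA~ < 1.
* **Scenario 2** — metabolic demand outscales gill supply, *b*~MR~ >
  *b*~GSA~, so the supply-to-demand ratio shrinks as the fish grows.

The discriminating statistic is the **scaling difference**
*b~S~ = b~GSA~ − b~MR~*: *b~S~* < 0 is the signature of scenario 2, while
*b~S~* ≥ 0 contradicts it.

This package implements the full measurement-to-inference chain needed to
evaluate these predictions in a two-temperature rearing experiment:
intermittent-flow respirometry processing (RMR, MMR, P~crit~), gill
morphometry aggregation (GSA and its components), allometric fitting
(slopes, *b~S~*, mass correction, Q~10~, FAS) and growth metrics — plus a
synthetic-data generator with known ground truth so every stage can be
validated end to end.

## Respirometry model

Dissolved oxygen is recorded at 1 Hz in percent air saturation inside a
closed (or intermittently closed) chamber. Oxygen uptake follows from the
depletion slope by standard closed-respirometry arithmetic,

MO~2~ (mg O~2~ h^−1^) = −slope (mg L^−1^ s^−1^) × *V*~eff~ (L) × 3600,

where *V*~eff~ is the system volume minus the fish's volume (density taken
as 1 g mL^−1^). Percent saturation converts to mg L^−1^ through the
Benson–Krause freshwater solubility fit (1 atm, salinity 0), valid for
0–40 °C; at 15 and 20 °C it gives 10.08 and 9.09 mg L^−1^, matching the
USGS DOTABLES reference. Conversion uses the trial temperature; no
within-trial temperature drift is modelled.

**Resting metabolic rate.** A resting trace is tiled into
flush/wait/measure cycles from its first timestamp. Only measure-phase
samples are used; the wait phase absorbs the nonlinear mixing lag after
the chamber reseals, and a trailing partial cycle is dropped
(`floor(duration / cycle length)` cycles in total). Each segment gets an
OLS slope with *R*² as the squared Pearson correlation; segments with
*R*² < 0.9 are discarded (a segment with no oxygen variance has undefined
*R*² and is likewise rejected). The filter applies to resting segments
only — the MMR window is not *R*²-filtered, since the threshold is defined
for resting depletion traces. RMR is the mean of the *k* = ⌈0.25 *n*⌉
smallest accepted MO~2~ values; the ceiling guarantees at least one value
and fixes the rounding rule the "lowest 25%" phrasing leaves open.

**Maximum metabolic rate.** After an exhaustive chase the chamber is
closed and MMR is the MO~2~ of the steepest OLS slope over every
contiguous 60 s window, sliding one sample at a time. The implementation
uses cumulative-sum normal equations and is verified in the tests against
an exhaustive per-window `lm()` search.

**Background respiration.** Microbial uptake is measured in the empty
chamber before the chase and after the hypoxia trial, interpolated
linearly in time, and subtracted from each estimate at its window
midpoint. Negative background rates are clamped to zero and corrected
MO~2~ values are floored at zero, both with warnings, and every clamp is
visible in the returned table. Whether MMR should also be corrected is
ambiguous in common practice; the default here is yes
(`background_correct_mmr = TRUE`), with a flag to disable.

**Critical oxygen tension.** P~crit~ uses the LLO construction: project
RMR as a line from normoxia to zero at anoxia, *L(P)* = RMR × *P*/100;
estimate MO~2~ in consecutive 2 %-saturation bins down the closed
drawdown; report the interpolated PO~2~ of the highest crossing after
which binned MO~2~ stays below the line. For a fish whose uptake follows
RMR above a conformity breakpoint *P*~c~ and RMR(*P*/*P*~c~)² below it,
the crossing sits analytically at *P*~c~²/100 — the estimator reproduces
this within one bin width. A trace that never drops below the line (an
exact oxyconformer) yields an undefined result flagged as such. P~crit~
is reported in percent air saturation throughout.

## Gill morphometry model

GSA is the product of three measurable components,

GSA = *L*~fil~ × *n*~lam~ × *A*~lam~,

with *L*~fil~ the total filament length on both sides of the head (mm),
*n*~lam~ the lamellar frequency counting both sides of a filament
(mm^−1^), and *A*~lam~ the mean bilateral lamellar area (mm²).
Measurements arrive binned: filaments on the eight right-side hemibranchs
are grouped into 5–7 bins of ~12 filaments, each represented by its median
filament. *L*~fil~ doubles the summed `count × median length` products.
Lamellar metrics are measured only on a reference hemibranch (default 4,
the posterior hemibranch of the second arch, chosen as representative and
configurable): per-bin base/tip frequencies are averaged (a simple,
unweighted mean of the two locations — the within-filament weighting is
not specified by the protocol, so the simplest choice is used), weighted
by bin filament length, and doubled; per-bin tip/middle/base areas are
averaged and weighted by per-bin lamella counts. One convention worth
stating to prevent double-doubling: frequencies are stored one-sided and
doubled at aggregation, areas are stored already bilateral.

Because GSA is an exact product, log~10~ GSA is the exact sum of component
logs, and by OLS linearity the fitted GSA slope equals the sum of fitted
component slopes (to ~10^−15^ in practice; the pipeline asserts ≤ 10^−10^).
Geometric isometry would predict component slopes 0.33 (length), −0.33
(frequency) and 0.67 (area), summing to *b* = 0.67; fishes typically beat
this mainly by keeping the frequency slope near zero.

## Allometric inference

All fits are OLS on log~10~–log~10~ axes, per temperature:
log~10~ *y* = *a* + *b* log~10~ *M*, with 95 % CIs from the *t*
distribution with *n* − 2 df (the CI method is a package choice; simple
OLS intervals are the field default). Temperature effects on scaling are
tested by pooling the two groups with a temperature indicator and an
indicator × log-mass interaction, whose coefficient is algebraically the
difference of the per-group slopes, with a partial *F* test.

Derived quantities:

* *b~S~* = *b*~GSA~ − *b*~MR~ per temperature and metric, with the
  scenario-2 verdict from its sign. It is reported as a point difference
  without a formal SE, matching how it is used in the field.
* Mass correction to a reference mass (default the 24.0 g geometric mean
  of the study design): MR~mc~ = MR × (*M*~ref~/*M*)^*b*^. The exponent is
  whatever the caller passes; the pipeline always passes the
  temperature-specific fitted slope, since a pooled slope would leak
  temperature differences into the correction.
* Q~10~ = (R~2~/R~1~)^(10/(T~2~−T~1~))^ on mass-corrected treatment means
  per time point; FAS = MMR~mc~/RMR~mc~ per fish.
* Growth: SGR = 100 Δln *M*/Δ*t* (% day^−1^), the instantaneous form
  consistent with exponential growth (chained intervals compose
  time-weighted, which the tests assert); relative condition factor
  *K* = 100 *M*/*L*^3.085^ with fork length in cm, the exponent being the
  population's empirical length-mass regression value, and the ×100
  scaling following the standard Fulton convention so users comparing
  against other conventions can rescale.

## What the synthetic generator emulates

The generator reproduces the *study conditions*: two temperatures (15 and
20 °C), initial masses 2.62 ± 0.80 g, sampling at 14, 90 and 180 days with
chamber volumes 0.657, 0.727 and 4.012 L, and latent traits scattered
log-normally (default σ = 0.05 in log~10~) around configurable true
allometric lines. Scenario presets encode the hypothesis space: the `null`
preset uses slopes like those observed (*b*~GSA~ = 0.97, *b*~RMR~ = 0.87,
*b*~MMR~ = 0.94, components 0.454/−0.036/0.552), `gol_scenario1` sets all
slopes to 0.80, and `gol_scenario2` sets *b*~MR~ = 0.95 over
*b*~GSA~ = 0.80. Latent GSA is defined as the exact product of the latent
components, so component-slope additivity is a structural property of the
data, as it is for real gills. Component intercepts anchor *L*~fil~ at
150 mm and *n*~lam~ at 60 mm^−1^ for a 1 g fish (realistic for a small
salmonid), with *A*~lam~ taking the remainder so intercepts sum exactly.

Design choices made where the real protocol is silent, all settled once:

* **Growth law**: exponential growth with SGR declining linearly in age
  (base 2.6 % day^−1^, decay 0.0025 day^−1^, temperature penalty
  0.044 °C^−1^). Only the SGR semantics matter downstream; these defaults
  land the cohort near 200 g at 15 °C and near 80 g at 20 °C after eight
  months, matching the scale of the experiment the generator emulates.
* **Diel variation**: resting uptake is elevated by a per-cycle rectified
  sinusoid (default amplitude 30 % of RMR, zero through the trough half of
  the cycle sequence). This makes the "lowest 25 %" estimator a meaningful
  target — and exactly recoverable at zero noise, because the trough
  cycles sit exactly at latent RMR. Real diel variation is continuous and
  the amplitude is a free parameter, not an estimate of real fish.
* **Chase recovery**: post-chase uptake holds at latent MMR for 90 s
  (longer than the 60 s rolling window, so the planted value is exactly
  recoverable) before decaying exponentially (τ = 300 s) toward RMR. Real
  recovery kinetics are unknown; only the plateau matters for validation.
* **Per-fish random streams** are derived by hashing the global seed with
  the fish id, so subsetting a cohort never changes another fish's data
  and every generator is byte-deterministic under a fixed seed.

What the generator does *not* emulate — tank effects, cortisol dynamics,
condition-factor trends, hydrodynamics, instrument drift — bounds what
passing tests can show: they validate the estimators and inference chain
against known truth under realistic noise, not the biology of any real
cohort.

## Numerical choices and degenerate inputs

* Cycle segmentation counts ⌊duration/cycle length⌋ cycles from the first
  timestamp; a trace shorter than one cycle returns an empty result with a
  warning rather than an error.
* Zero time-variance segments are rejected; zero O~2~-variance segments
  return slope 0 with NA *R*² and are never accepted.
* P~crit~ binning needs ≥ 3 samples and positive variance per bin; the
  crossing is linearly interpolated between bin midpoints, and a trace
  already below the line in its highest bin reports that bin's midpoint.
* Effective volume ≤ 0 (fish bigger than the chamber) is rejected, as are
  non-positive masses or trait values in any fit, with row numbers.
* The drawdown generator integrates the closed chamber by forward Euler at
  the sample rate; at 1 Hz the discretization error is far below the 2 %
  bin width of the estimator.

## Problem sizes used in validation

The shipped tests and the acceptance script choose sizes that keep the
full validation cheap while leaving comfortable statistical margins:
cohorts of 36 fish per temperature (12 per sampling day) for the
100-seed slope-recovery and verdict studies, 18 per temperature for the
end-to-end pipeline demonstration, 100 random 2-minute traces for the
rolling-regression/brute-force equivalence, and single fish for the exact
round-trip identities. CI coverage at 95 % nominal over 100 seeds is
required to reach only 90, the binomial 99.9 % lower band.

## Known limitations

* Growth inference is deliberately simple (SGR, condition factor,
  treatment summaries); mixed-model growth analyses with time-varying
  dispersion are out of scope, as are post-hoc marginal-means contrasts —
  users can feed `per_fish` tables to `glmmTMB`/`emmeans` directly.
* The LLO P~crit~ depends on the supplied RMR; errors in RMR propagate
  linearly into the reference line.
* `b_S` carries no formal uncertainty here; a bootstrap over fish is easy
  to add on top of `fit_power_law()` if needed.
* The morphometry module starts from bin-level measurements; image
  analysis (filament tracing) is upstream of this package.
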