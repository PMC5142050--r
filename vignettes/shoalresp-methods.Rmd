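---
title: "Models and methods behind shoalresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shoalresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoalresp)
```

shoalresp implements the computational chain of an ocean-acidification
study on a shoaling damselfish: treatment chemistry, intermittent-flow
respirometry, metabolic summary statistics, choice-arena scoring, and the
mixed-model inference layer, all validated against a synthetic-data
generator with recorded ground truth. This vignette documents the models,
the tunable parameters and their defaults, the numerical choices, and the
limits of what the synthetic validation can show.

## 1. Seawater carbonate system

Treatment tanks are dosed to a target NBS pH; the experienced pCO2 is
solved from the measured pair (pH_NBS, total alkalinity) at the tank's
temperature and salinity. The solver works on the seawater (SWS)
hydrogen-ion scale throughout:

* K1, K2: Mehrbach constants as refit by Dickson & Millero (SWS);
* KB: Dickson boric acid (total scale, converted to SWS); KW: Millero;
* K0: Weiss CO2 solubility; KS: Dickson bisulfate; KF: Dickson & Riley;
* total boron from salinity (Uppström); fH: Takahashi activity factor.

These are the defaults of the classic CO2SYS configuration for this kind
of husbandry work; the choice is recorded in every result object for
provenance. NBS pH converts to the working scale by
$[\mathrm{H^+}]_{SWS} = 10^{-pH_{NBS}} / f_H$. Given the hydrogen ion, all
non-carbonate alkalinity terms (borate, hydroxide, free hydrogen,
bisulfate, fluoride) are explicit, so carbonate alkalinity follows by
subtraction and DIC in closed form:

$$\mathrm{DIC} = CA\,\frac{H^2 + K_1 H + K_1 K_2}{K_1\,(H + 2K_2)},
\qquad p\mathrm{CO_2} = \frac{[\mathrm{CO_2^*}]}{K_0}.$$

Because the pH+TA input pair admits this closed form, no iteration is
needed; the forward direction (pH from TA and DIC, `ph_from_ta_dic()`)
uses bounded root-finding and serves as a round-trip check. Pressure is
fixed at the surface and nutrient alkalinity at zero (none is measured in
this setting; the solution is identical when nutrients are absent). The
fugacity correction (~0.3% at these levels) is off by default and exposed
as a flag; both conventions lie well inside the tolerance with which
printed treatment tables can be reproduced. Reproduction of published
treatment-table pCO2 from printed mean inputs is limited by the rounding
of those inputs (pH to two decimals is ±1.2% in pCO2 by itself); the
package reproduces a six-row reference table to within 1.7% on every row,
with no systematic bias.

## 2. Respirometry processing

A trial alternates sealed measurement phases (default 540 s) with flushes
(default 180 s); O2 is logged every 2 s. Processing decisions:

* **Segmentation is clock-based** (the apparatus cycles pumps on a fixed
  timer); a detection-style path through `segment_trace()` remains
  available for QC. The leading 60 s of each measurement phase are dropped
  by default — the flush-to-measure transition is not instantaneous — and
  both the discard and the phase lengths are configurable.
* **Slopes** are ordinary least squares of concentration on time, rescaled
  to mg O2 L⁻¹ h⁻¹. On a regular sampling grid all windows are fit in one
  closed-form pass; the result is identical to per-window `lm()` fits
  (verified in the tests to 1e-10).
* **MO2 = |slope| · V_eff**, with V_eff the chamber-plus-tubing volume
  (default 100 ml) minus the fish's volume at density 1 g/ml (a ~1%
  effect; a flag disables the subtraction). Windows with r² < 0.9
  (configurable) or oxygen-increasing slopes are flagged invalid and
  excluded downstream, never silently deleted.
* **Background respiration** is measured in the empty chamber for three
  periods before and after the trial; the correction assumes the
  background O2-decline rate grows linearly between the pre- and
  post-trial means and subtracts the interpolated rate times V_eff from
  each record. Corrected values below zero are floored and flagged.

## 3. Metabolic summary statistics

* **MR_min** — the "lowest 10th percentile" of all MO2 measurements is
  read as the *mean of the lowest decile* (the convention of the standard
  SMR-quantification literature); the 10%-quantile-point alternative is
  exposed via `method = "quantile"`. MR_min deliberately uses *all*
  measurements, including the first five hours.
* **RMR** — mean MO2 excluding the first 5 h (the habituation window over
  which MO2 decays to a stable level).
* **FS / ISR** — FS is the first valid window of the trial, directly after
  transfer; ISR = (FS − MR_min)/AS expresses handling stress as the
  fraction of aerobic scope it consumes. Values outside [0, 1] are
  returned with a flag, not clamped.
* **MMR** — greatest windowed uptake (180 s windows, non-overlapping by
  default, rolling available) during the 8–10 min post-chase recovery;
  AS = MMR − MR_min holds identically on every summary row.
* **Calming effect** — 100·(MR_min,alone − MR_min,group)/MR_min,alone; an
  increase under group testing yields a negative reduction by the same
  formula.
* **Mass correction** (figures only): residuals of log10(rate) on
  log10(mass) added to the fitted value at the 1.29 g reference mass and
  back-transformed. Inference always runs on whole-animal values with mass
  as a covariate, so the correction never touches the statistics.

## 4. Choice-arena scoring

The arena is 90 × 30 cm with a stimulus container (10 cm diameter) 6 cm
from each end wall. A fish is associating when it is within two body
lengths of the container's *outer wall* (the shoal occupies the
container), i.e. within container radius + 2·SL of the centre; standard
length is used, as that is what such studies measure. Scoring is per
sample at the trajectory's native rate in 2-D (top view): time-in-zone
proportions (plus the preference share
time_familiar/(time_familiar + time_unfamiliar), whose no-preference null
is exactly 0.5), the zone of first entry, and visits as entry events. An
optional two-sample debounce mimics a human video scorer's suppression of
boundary jitter. Trials that never visit both zones fail the informed-
choice filter and are flagged for retest, never imputed.

## 5. Inference layer

* **Preference**: per treatment, deviation = preference − 0.5 in an
  intercept-only LMM with a random shoal intercept (fish are nested in
  shoals); the intercept's Satterthwaite t² is reported as an F. With a
  degenerate grouping the function falls back to a one-sample t-test and
  records that in its `method` column.
* **Initial choice**: binomial GLMM (treatment fixed, shoal random), Wald
  χ². Complete separation triggers a penalized fixed-effect logistic
  fallback (half-weight pseudo-observations per treatment cell), with a
  warning.
* **Within-fish endpoints** (MR_min, RMR, ISR, activity): Gaussian LMM
  with CO2 × testing, body mass, and a random fish intercept; marginal
  type-III F tests with Satterthwaite denominator df. The approximation is
  named in every output row; on the balanced 30-fish paired design it
  reproduces the design arithmetic (interaction denominator ≈ 26).
* **Once-per-fish endpoints** (MMR, AS): Gaussian fixed-effects model with
  mass covariate, type-II F.
* **Tukey contrasts** on the three-level CO2 factor via estimated marginal
  means, reporting adjusted and raw p-values.

All of this stands on lme4/lmerTest, car and emmeans — the model families
the original analyses in this literature use.

## 6. The synthetic-data generator

The generator defines the study conditions; its defaults are fixed once:

| parameter | default | rationale |
|---|---|---|
| design | 3 CO2 levels × 10 fish, both testing treatments | study design |
| mass | N(1.29, 0.22) g, truncated to [0.7, 1.9] | printed mean/SEM; cohorts are size-matched |
| SMR allometry | 0.49·mass^0.8 → 0.60 mg O2/h at 1.29 g | typical juvenile damselfish at 29 °C |
| SMR scatter | lognormal CV 0.20, truncated ±2 SD | typical between-individual CV |
| stress | +100% at t = 0, τ = 1.5 h | trials stabilise within ~5 h |
| activity | per-phase Exp(0.10) excess | routine mean ≈ 0.66 = 1.1 × SMR |
| calming | ×0.772 on basal rate in group testing | the 22.8% reduction under study |
| aerobic scope | MMR = 3 × SMR, recovery τ = 450 s | typical factorial scope of 3 |
| trace | 17–19 h, 2 s sampling, noise sd 0.01 mg/L, saturation 6.4 mg/L | apparatus |
| background | 0.005 → 0.02 mg O2 L⁻¹ h⁻¹, linear | slow microbial growth |
| choice | sojourn 14 s / transit 6 s, uninformed 22%, shoal sd 0.15 logit; p_familiar 0.65 control / 0.50 elevated | ≈ 45 visits per 15 min; preference only in control |

Instantaneous MO2 is SMR·calming·(1 + A·e^(−t/τ) + activity): handling
stress and spontaneous activity enter *additively* as fractions of basal —
elevated fractions of aerobic scope, not multipliers of each other, which
keeps extreme draws physiologically bounded. During sealed phases the
chamber O2 declines at (MO2/V_eff + background); flushes relax O2 toward
saturation with a 30 s time constant (affecting only samples the
processing discards). A trial whose O2 would fall below 2 mg/L raises a
generator error, mirroring the protocol's hypoxia constraint.

Choice trials are a continuous-time two-state-plus-neutral sojourn
process; each visit targets the familiar zone with probability p_familiar
(shoal-level logit noise on top). With probability 1 − 0.22 the visit
sequence is conditioned to include both zones (matching the retest
eligibility rule); uninformed trials keep to a single zone and trigger
simulated retests with fresh randomness. The event sequence is emitted as
a positional walk consistent with zone membership; scored zone time runs
slightly above the event-sojourn bookkeeping because the tail of each
approach transit already lies within two body lengths — which is exactly
what a human scorer would count.

Master seeds fan out deterministic child seeds, so identical
configurations reproduce byte-identical datasets at every granularity.

**What passing recovery tests does and does not show.** The generator
emulates the schedule, noise structure and effect sizes of a real study,
so parameter recovery demonstrates that the estimators are unbiased and
appropriately precise *under the stated model*: exponential stress decay,
phase-constant activity, linear background growth, Gaussian sensor noise,
exponential sojourns. Real traces have features the generator omits —
optode drift and temperature sensitivity, autocorrelated activity bouts,
nonlinear background growth, video-tracking noise — so recovery here
validates the computational chain, not the field protocol.

## 7. Numerical choices and degenerate inputs

* Alkalinity solve: closed form; implied non-positive carbonate alkalinity
  is a domain error. Round trips (pH → DIC → pH) hold to 1e-4 pH units.
* Slope fits require ≥ 10 points and nonzero time variance; constant-O2
  windows report slope 0 with r² = 1 (a perfect fit of a flat line).
* MR_min requires ≥ 10 measurements; the decile size is ⌈n/10⌉.
* Zero-variance responses in the inference layer return explicit
  degenerate-fit notices rather than statistics; failed mixed-model fits
  degrade the same way instead of erroring.
* Mass correction with all masses equal returns the values unchanged
  (zero-leverage identity) rather than attempting a singular regression.
* Problem sizes used in the validation suite: 100 simulated fish for
  estimator recovery, 102 pairs plus 100 cohorts of 30 fish for the
  calming analysis, 500 scored trials and 1000 event-level replicates for
  the behavioural calibration — chosen to give Monte-Carlo error well
  inside each tolerance.

## 8. Known limitations

* The carbonate module implements only the pH+TA input pair at surface
  pressure; it is a treatment-chemistry tool, not a general CO2-system
  package.
* Mixed-model p-values use the Satterthwaite approximation; other software
  conventions (e.g. different denominator-df bookkeeping for per-treatment
  preference tests) will differ slightly, so the df are always reported
  rather than forced to match any particular convention.
* ISR can legitimately exceed 1 when the first-window uptake tops the
  windowed MMR estimate (MMR's window average is biased low on a decaying
  recovery); the value is flagged, and interpretation is left to the
  analyst.
* The trajectory emitter is built for scoring fidelity, not for modelling
  swimming kinematics.
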