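---
title: "Modelling the heart-rate slow component: methods and design choices"
author: "hrsc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the heart-rate slow component: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrsc)
```

## The problem

During constant-work-rate exercise, oxygen uptake (V̇O₂) settles at a steady
state within a few minutes, but heart rate does not: beyond roughly the fifth
minute it keeps rising at a slow, approximately linear rate — the heart-rate
slow component, scHR, expressed in bpm·min⁻¹. The scHR grows with relative
exercise intensity, is smaller in females, and declines with age. When
exercise is prescribed through fixed HR targets, this drift forces a
progressive reduction of the work rate, eroding the metabolic stimulus the
prescription was meant to hold constant.

`hrsc` implements the full analysis chain around a linear prediction model
for the scHR:

$$ \mathrm{scHR} \;(\mathrm{bpm\,min^{-1}}) = -0.0514 + 0.0240\cdot\%\mathrm{RCP}
   - 0.0172\cdot\mathrm{age} - 0.347\cdot\mathrm{sex} $$

with sex coded male = 0, female = 1, and %RCP the fifth-minute V̇O₂ expressed
as a percentage of the V̇O₂ at the respiratory compensation point (RCP). The
model's development fit reports r² = 0.53 and a standard error of estimate
(SEE) of 0.61 bpm·min⁻¹; the constant lives in `published_schr_model()` and
is evaluated by `predict_schr()`.

Intensity is anchored to the individual's ventilatory landmarks: the gas
exchange threshold (GET, lower boundary of the heavy domain) and the RCP
(lower boundary of the severe domain). Moderate, heavy and severe trials sit
at fixed fractions of the rest→GET, GET→RCP and RCP→V̇O₂max spans
(`target_vo2()`), and the corresponding power output comes from inverting the
ramp-derived, mean-response-time-corrected V̇O₂/power relation
(`vo2_to_po()`).

## The synthetic-data generator

The original breath-by-breath recordings are not publicly deposited, so the
package carries a first-class generator whose defaults *are* the study
conditions and give every downstream stage a known ground truth.

**Subjects** (`generate_population()`). Profiles are drawn in age/sex strata
(development plan: 65 subjects — 23 young with 12 females, 22 middle-aged
with 12 females, 20 elderly with 10 females; any other total is apportioned
by largest remainder). Defaults mimic the development cohort: relative
V̇O₂max Normal(51.0, 11.0) mL·min⁻¹·kg⁻¹ in males and Normal(41.4, 7.1) in
females; GET fraction Normal(0.621, 0.071) and RCP fraction Normal(0.845,
0.060) of V̇O₂max, jointly truncated to 0 < GET < RCP < 1 with a 0.03
separation margin; HRmax centred on the age-predicted 208 − 0.7·age with an
8-bpm residual SD; resting V̇O₂ at 3.5 mL·min⁻¹ per kg body mass; the
V̇O₂/power gain Normal(10.1, 0.8) mL·min⁻¹·W⁻¹; the ramp mean response time
Normal(40, 10) s. A validation-cohort configuration
(`step2_population_config()`) matches the independent sample's moments.

**Constant-work trials** (`simulate_constant_trial()`). Each trial emits a
3-min freewheeling baseline and an instantaneous step to the target power.
V̇O₂ follows a mono-exponential with domain-specific time constants (30, 35,
40 s for moderate/heavy/severe — invented, configurable); HR follows a
mono-exponential (35, 40, 45 s) to a primary steady state, then drifts
linearly from 300 s after onset at the trial's true slope. Two modelling
choices deserve emphasis:

* *The primary HR component is treated as complete at the slow-component
  onset.* Writing the exponential as continuing underneath the drift would
  contaminate the post-300-s trace with a decaying ~0.02 bpm·min⁻¹ curvature
  and make the generator inconsistent with the measurement model (a pure
  linear fit from minute 5). Freezing it at its 300-s value (≥ 99.87% of the
  amplitude for τ ≤ 45 s) makes the measured slope identical to the generated
  one in a noiseless world, which is what turns every closure test into an
  exact one.
* *The primary HR gain is calibrated to the reported fifth-minute HR.* The HR
  reserve fraction is an affine map of the V̇O₂ reserve fraction,
  0.08 + 0.80·f. A naive 1:1 mapping would put severe-trial HR at ~96% of
  HRmax — well above the ~89% the development data show — and would make the
  HRmax ceiling clip the generated drift.

The true slope is the prediction equation evaluated at the trial's nominal
%RCP plus a Normal(0, `sigma_resid` = 0.61) residual. By default the slope is
*not* truncated at zero: truncation would turn the generating model into a
censored one, max(0, Xβ + ε), and ordinary least squares on censored data
cannot recover β — which would defeat the purpose of a recovery harness built
around a linear refit. Slightly negative realised slopes are physiologically
plausible readings of measurement-level drift at easy intensities. For
experiments that want hard non-negativity, `noise_config(truncate_negative =
TRUE)` restores the censored behaviour, and the realised value is always
stored in the trial's ground-truth ledger.

**Noise model** (`noise_config()`). Additive per-breath HR noise (SD 2 bpm),
multiplicative gas-channel noise (3% of signal), breath intervals
Uniform(2, 4) s, and a constant per-trial HR offset with SD 1.7 bpm
representing day-to-day variability. The offset is what makes the
within-subject freewheeling HR coefficient of variation land in the reported
~2.7% range — per-breath noise alone averages out to ~0.4% across visits. It
cancels exactly in the slope and in the measured-minus-projected end-HR
difference.

Breath samples are emitted exactly at the trial start, exercise onset,
slow-component onset and trial end. With those anchors, piecewise-linear
signals survive 1-s interpolation and 5-s binning exactly, so pipeline
invariance can be asserted at 10⁻⁶ rather than at some loose tolerance.

**What the generator does not emulate.** No V̇O₂ slow component above GET, no
cardiovascular drift beyond 15 min, no thermoregulatory or catecholamine
mechanisms, no ectopic beats or RR-interval structure, no device-specific
artefact shapes; aberrant points are injected synthetically
(`inject_aberrant()`) as displacements from the local trend. Passing tests
therefore demonstrate that the estimators and the pipeline are correct and
unbiased under the stated generating model — not that the model captures
every feature of real breath-by-breath data.

## Cleaning

`clean_trial()` applies the standard three stages:

1. **Outlier rejection** (`remove_aberrant()`): per channel, ordinary
   least-squares lines over the baseline window (−180–0 s around onset) and
   the steady-state window (180 s–end); points further than `sd_mult` (default
   3) residual SDs from their window's fit are removed. The early transition
   (0–180 s post-onset) is never touched, and fitting is single-pass — the
   windows are not refitted after removal, the simpler of the two readings of
   the source procedure. The residual SD uses the n − 2 denominator. Removal
   is per-channel: a breath flagged in HR keeps its V̇O₂.
2. **1-s linear interpolation** (`interpolate_1s()`), integer grid, source
   values at integer times preserved exactly.
3. **5-s binning** (`bin_5s()`): windows [5k, 5k+5) reduced by the mean
   (median available — the source wording is ambiguous between the two; the
   mean is the default reading), timestamped at the window centre so that
   slopes fitted on binned data are unbiased.

## Per-trial metrics

`compute_schr()` fits HR against time-in-minutes over minute 5 to the end of
exercise, inclusive; "at the fifth minute" quantities (`window_value()`) are
means over the 30-s window ending at minute 5, matching the 30-s convention
used for ramp maxima; the oxygen pulse is the ratio of the window means, not
the mean of per-breath ratios (lower variance). The fit runs on the 5-s
binned series; whether the original analysis used bins or second-by-second
data is not stated, and the choice is inconsequential for an OLS slope.

## Ramp analysis

`max_params()` averages V̇O₂ and the breath-wise respiratory exchange ratio
over the final 30 s and takes the highest HR. `compute_mrt()` measures the
time shift between the ramp's power profile and the fitted V̇O₂/time line
using the steady-state V̇O₂ of the pre-ramp baseline bout: the mean response
time is the time at which the fitted line reaches that steady state minus the
time at which the ramp power equals the baseline power, clamped at zero. A
lagging V̇O₂ response yields a positive MRT, and the estimate is invariant to
the ramp rate when the underlying lag is fixed. The published external model
for the additional above-GET slow-component power correction is out of scope;
`vo2_to_po()` instead exposes a single configurable gain `sc_gain`
(mL·min⁻¹·W⁻¹, default 0 = MRT-only correction) added to the ramp slope for
the above-GET portion. GET and RCP are always inputs (known truth for
synthetic subjects); expert visual threshold detection is not reimplemented.

## Model fitting

`forward_select()` implements forward multiple regression with collinearity
screening: at each step the candidate with the smallest partial-F p-value
below `alpha_in` (0.05) enters; after each entry, pairwise |Pearson r| and
variance inflation factors among the included predictors are checked against
`r_cut` (0.70) and `vif_cut` (5). From a violating pair, the member whose
removal costs the model less explanatory power (residual sum of squares) is
discarded from the model and from further candidacy. Entry order alone is
*not* used as the tie-break: the fifth-minute V̇O₂ — a collinear proxy that
carries intensity plus some sex and age signal — enters one step before %RCP
in a non-trivial fraction of simulated datasets, and discarding the later
entrant would then throw away the genuine predictor. The explanatory-power
rule reproduces the original analysis, which discarded the cross-correlated
candidates (fifth-minute V̇O₂, HRmax, relative V̇O₂max) after verifying that
their removal did not reduce the model's fit. The SEE uses the n − p − 1
denominator; selection stops when no candidate qualifies or the fit is
numerically perfect (RSS below 10⁻¹⁰ of the total sum of squares — the
relevant guard for zero-noise worlds, where partial-F statistics on an
exactly-fitted response are numerically meaningless). Observations pooled
across trials within subject are treated as independent, as in the original
pooled OLS; no mixed-effects structure is fitted.

`recover_parameters()` composes the whole chain — population → six
domain-anchored trials per subject → cleaning → metrics → forward selection —
and returns the fitted model next to the generating truth. With all noise
zero, the intensity, age and sex effects are recovered to better than 10⁻³;
the intercept carries an additional ≈ −10⁻³ bpm·min⁻¹ shift because the
fifth-minute V̇O₂ window reads the mono-exponential 0.01–0.09% short of its
asymptote, so measured %RCP is deterministically ~0.999× the nominal value at
which the truth was generated. This is the same convention the original
analysis uses (%RCP from the measured fifth-minute V̇O₂), so the shift is
kept and documented rather than "corrected".

## Validation (Step 2)

`run_step2()` simulates the independent cohort (36 subjects, three trials at
50% of each domain's span, 15/12/9 min for moderate/heavy/severe), projects
the end-exercise HR as HR@5min + scHR·(t − 5) with the model-predicted slope,
and compares projections against measured end-exercise HR via
`bland_altman()`: bias (measured − estimated, so positive = under-prediction),
sample-SD of differences, limits of agreement bias ± 1.96·SD (exact
identities), the squared Pearson correlation, and a z-score defined as
bias/SD. The z-score definition is documented as nonconforming: the source
reports a value that is not reproducible from its own bias and SD under any
standard definition, so the package fixes the identity-based one. Window
means represent their temporal centres, so the projection targets the centre
of the last-minute window — projecting to the nominal end time against a
window mean would build in a spurious −scHR/4 offset. In a zero-noise world
the remaining bias is the fifth-minute window's exponential tail, bounded by
0.1 bpm.

`within_subject_cv()` reports the per-subject CV of freewheeling HR across
visits, the repeatability statistic of the protocol.

## Reproducibility and problem sizes

Every stochastic function takes a `seed` and restores the caller's RNG state;
`seed = NULL` consumes the current stream so composite pipelines
(`run_step1()`, `run_step2()`, `recover_parameters()`) seed once and are
bit-reproducible end to end, which the manifest written next to each artifact
records. The test suite exercises: populations up to 10⁴ subjects for
moment convergence; 10⁴ simulated trials for slope-estimator unbiasedness;
200 seeded replicates of the full 65 × 6 recovery for confidence-interval
coverage; and 1000 null datasets for the forward-selection type-I rate.

## Known limitations

* The generating model is linear and additive; real scHR may be nonlinear in
  intensity near domain boundaries, and the equation's external validity
  beyond moderately active adults is untested here.
* Pooled OLS ignores within-subject correlation; standard errors for
  between-subject predictors (age, sex) would widen under a mixed model.
* The `sc_gain` power correction is a one-parameter stand-in for a richer
  published correction model and defaults to 0.
* Aberrant-point injection displaces samples from the local trend by a fixed
  multiple of the local SD — real artefacts (swallows, coughs, sensor
  dropouts) have richer structure, so cleaning efficacy on real data may
  differ from the synthetic figures.
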