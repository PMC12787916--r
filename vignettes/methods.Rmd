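---
title: "Methods: from force trace to normative benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from force trace to normative benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcsbench)
```

mcsbench analyses maximal voluntary isometric contraction (MVC) forces
recorded on a platform-mounted triaxial force sensor while a person
stands on it and pushes or pulls as hard as they can in one of six
standardized directions.  This vignette is the package's account of
the science: the measurement model, the extraction procedure that
defines the strength score, the statistical benchmarking layer, the
synthetic cohort that stands in for raw recordings, and the numerical
choices made along the way.

## The measurement chain

Each axis of the sensor is a strain-gauge Wheatstone bridge whose
differential output (about 10 mV at full load) is conditioned by an
instrumentation amplifier and digitized by the microcontroller's ADC.
The package models this chain statically — settled values, no feedback
simulation — because the analysis only needs the arithmetic, not the
dynamics:

* the sensor supply regulator, `V_out = V_ref (1 + R2/R1)`, trimmed
  over 9.950–10.050 V in 1000 PWM steps (100 µV/step);
* the amplifier, `V_out = G (V+ − V−) + V_ref`, with `G = 360`
  lifting the bridge signal into the 3.6 V ADC range and a mid-rail
  offset of 1800 mV so that tension and compression share one
  single-polarity rail.  Rail saturation is flagged metadata, not an
  error: a maximal effort may legitimately clip, and the pipeline has
  to report that rather than hide it;
* the ADC grid, `LSB = supply / 2^bits` (0.055 mV at 16 bits and
  3.6 V; the noise-free 14-bit figure, 0.22 mV, is available behind a
  flag), with `quantize()` rounding to the nearest grid point so the
  round-trip error bound `gain_factor × LSB / 2` is testable;
* the per-axis force calibration, `F = (ADC_mV − ZeroOffset) ×
  GainFactor`, with the zero offset measured unloaded and the gain
  factor from a known reference weight.  ADC values are interpreted in
  millivolts with `ZeroOffset = 1800` mV — half the 3.6 V supply —
  which keeps the zero-force point dimensionally consistent with the
  amplifier offset.  Axes are calibrated independently; no cross-axis
  coupling is modelled.

One stated design figure is internally inconsistent: a 0–2.32 V
reference trimmed over 50,000 counts gives 46.4 µV/step, not 5 µV.
`regulation_resolution()` always computes from range and counts and
does not reproduce the 5 µV figure.  Likewise the hardware is
described both as piezoelectric and as strain-gauge bridges; the
bridge path carries all the formulas and is the one modelled.

## The strength score

A trial's score is deliberately *not* the highest sample.  The trace
is low-pass filtered (Butterworth, 15 Hz cutoff — voluntary force
content lives well below 10 Hz) and then scanned with a sliding
window: the MVC is the highest mean force sustained over any
continuous 1.5 s segment, wherever in the trial it occurs.  A
single-sample artifact of 1000 N on a 100 N plateau moves the score
to 100.43 N, not 1000 N.  Per direction, three trials are recorded
and the best windowed mean is kept; the best is divided by body mass
to give relative strength in N/kg, the unit all benchmarking uses.

Numerical choices, each a config knob:

* **Filter order 4, applied zero-phase (forward–backward).**  The
  order is not dictated by the protocol; 4th order is the
  biomechanics convention, and zero-phase application avoids lag
  between the window position and the effort.  The effective
  magnitude response is 8th order.
* **Edge handling.**  The `signal` package's `filtfilt` starts both
  passes from zero state, which visibly corrupts trace ends, so
  `lowpass_filter()` extends the signal by odd reflection about its
  end samples — 12/cutoff seconds of padding (≈1120 samples at the
  defaults), enough for the startup transient to decay below 1e-9 —
  and discards the padding.  A constant trace passes through
  unchanged to better than 1e-9 N.
* **Window placement step 1 sample** ("any continuous segment"
  implies dense placement); a larger step is available for speed and
  is tested against a stepped oracle.
* **Ties** between equal window means go to the earliest window, for
  determinism.
* **Sign.**  Each direction maps to one axis (`fx` for the frontal
  pair A/B, `fy` for the sagittal pairs D1/D2 and K1/K2) and one
  polarity; the channel is multiplied by the direction's effort sign
  before filtering, so push and pull remain distinct tests and a
  correctly performed effort scores positive.  The window mean is
  taken on this signed component, never on the absolute value.
* **Whether the best-of-three is taken over windowed means or raw
  peaks** is ambiguous in the protocol's wording; the windowed-mean
  reading is used throughout, since the window *defines* the score.

Normalizing mass defaults to the participant record (the cohort
tables are mass-measured), with `mass_from_fz()` — quiet-stance
vertical force divided by g = 9.81 m/s² — as the platform-only
alternative.  Frontal-plane forces are treated as a single platform
resultant, not summed per foot.

## The statistical layer

Group summaries are means and SDs of relative strength per stratum
(sex × age group: G25 = 20–30 y, G45 = 40–50 y, G65 = 60–70 y) and
direction.  Differences between means are reported as percentages of
the reference mean, `100 (M1 − M2) / M2`.  Sex comparisons use the
independent-samples t-test (pooled-variance Student by default, Welch
by flag).  Age trajectories per sex use one-way ANOVA followed by
Games–Howell post hoc pairs — unpooled standard errors,
Welch–Satterthwaite degrees of freedom, p-values from the studentized
range distribution with k groups, which at k = 2 collapses exactly to
the Welch t-test.  The sex × age design uses a two-way ANOVA with
partial eta squared, `SS_effect / (SS_effect + SS_error)`.

Sums of squares are computed by model comparison on the design
matrix: Type II by default (each main effect against the additive
model), which coincides with the classical decomposition when cells
are balanced; Type III under sum-to-zero contrasts behind a flag.
The decomposition is computed directly rather than through a wrapper
so that saturated fits (zero residual variance, as in noiseless
synthetic cells) still yield well-defined sums of squares; the
`car::Anova` implementation serves as an independent cross-check in
the test suite, not as the implementation.  A published
reference t-statistic reported as t(30) alongside group sizes of
17 + 17 is noted as inconsistent (df should be 32) and not imitated.

No multiple-testing correction is applied across the six directions
by default, matching common practice in normative studies; a
Bonferroni flag exists.  α = 0.05 throughout.

The clinical product is the normative table — stratum × direction →
(n, mean, SD) — and the deficit report scoring a patient against it:
z-score, percent-of-norm, and percent deficit relative to the stratum
mean.

## The synthetic cohort

No raw recordings are distributable, so the generator is first-class,
tested code, and its defaults *are* the study conditions:

* **Strata and sizes.**  Men 19/17/15 and women 18/17/15 across
  G25/G45/G65 (N = 101).  The source counts are slightly
  inconsistent between the overall and per-group reports (48 vs 50
  women), so n is a config knob; the per-group counts are the
  default.
* **Anthropometrics.**  Height and mass are drawn per stratum from
  normal distributions with the reported means and SDs, truncated to
  the reported ranges; age is uniform over the stratum decade; BMI is
  recomputed from the draw.
* **Cell means.**  Within each direction the 6 cell means are built
  additively — female-G25 baseline + male offset + age offset — so sex
  and age do not interact by construction, matching the near-null
  interaction terms the two-way analysis reports.  The anchors
  reproduce published values exactly where they are printed
  (direction A young adults: 1.8504 vs 1.3659 N/kg; direction D2
  middle age: 2.3039 vs 1.6909 N/kg) and published percent
  differences elsewhere (male advantages of ~16–36%, age declines of
  ~25–45% concentrated after 50, strongest in the pull directions).
* **Spread.**  Within-stratum SDs are never published.  The default,
  0.35 N/kg across all cells, was chosen once as a value that makes
  the published percent differences detectable at the published group
  sizes — a documented assumption, not a reproduction.
* **Traces.**  A maximal effort is a 0.5 s quiet baseline, a 1 s
  C2-smooth ramp, and a 3 s plateau at the target force (the window
  needs 1.5 s of it), overlaid with band-limited 8–12 Hz Gaussian
  tremor at 2% of target (below the 15 Hz cutoff, so the filter is
  exercised meaningfully), 1% wideband noise, and sparse single-sample
  spikes (0.5/s, up to half the target) that the window must reject.
  Everything is seeded; the same configuration reproduces the same
  cohort bit for bit.

What the generator does *not* emulate — and hence what passing tests
do not show about real data: musculoskeletal dynamics, fatigue across
trials, balance corrections correlated across axes, inter-trial
learning, and any non-normality of real strength distributions.  The
generator validates the pipeline's arithmetic and its statistical
calibration, not human physiology.

## Problem sizes and verification

The test suite and the acceptance script re-derive every headline
number at run time.  Deterministic identities (F = t² for two groups,
Games–Howell k = 2 vs Welch, balanced sum-of-squares decomposition,
window-oracle equivalence on 100 random traces against an exhaustive
loop) run at full precision.  Stochastic checks use fixed seeds and
pre-registered bands: full-pipeline recovery of all 36 stratum ×
direction means within 2 standard errors at the study group sizes;
≥90% power for the young-adult direction-A sex comparison over 100
cohort replicates; and a 5% ± 2% type-I rate for the gender main
effect over 1000 null-cohort replicates (score-level simulation, no
traces, for the replicate loops).  The published six-direction ANOVA
table is checked for internal self-consistency — recomputing F and
partial eta squared from the printed sums of squares — within 0.5%
relative tolerance, widened only by the propagation of the table's
own 2-decimal rounding, which dominates for the near-zero interaction
terms.

## Known limitations

* The normative defaults describe non-professional-athlete volunteers
  in three age decades; they are not population norms and should not
  be extrapolated to clinical or sedentary groups.
* Percent-difference defaults between printed anchors interpolate the
  published summary ranges; cells without a printed anchor are
  plausible, not reproduced.
* The acquisition chain is modelled at settled values; transients,
  RS-485 framing and real-time behaviour are out of scope.
* Deficit scoring assumes the stratum norm is approximately normal;
  with n of 15–19 per stratum the z-scores are indicative, not
  percentile-exact.
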