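---
title: "Computing and comparing actigraphy activity metrics"
author: "actimetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing and comparing actigraphy activity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actimetr)
```

## The problem

A wrist-worn accelerometer records three axial acceleration components at
1–100 Hz for days at a time. Almost no downstream user works with that raw
signal: it is reduced to one *activity value* per epoch (here 60 s), and
the reduction is anything but standardized. The raw axes may be band-pass
filtered or not; gravity may be removed by filtering or by normalizing the
vector magnitude; the metric may run per axis or on the magnitude, and the
magnitude may be computed before or after the filter. Each route produces
a different "activity" signal, and results computed along different routes
are routinely compared as if they were the same quantity.

`actimetr` makes the whole determination pipeline explicit so those
choices can be examined. This vignette records the models implemented,
the defaults and why they were chosen, the numerical decisions, and what
the synthetic validation data can and cannot show.

## Preprocessing model

From a `raw_recording` (axes in g, uniform sampling), `build_datasets()`
derives:

| kind | construction |
|------|--------------|
| UFX/UFY/UFZ | raw axial series |
| UFM | `sqrt(x² + y² + z²)`; carries the 1 g gravity offset |
| UFNM | `abs(UFM − 1)`; gravity removed without filtering |
| FX/FY/FZ | per-axis Butterworth band-pass |
| FMpre | magnitude of FX/FY/FZ |
| FMpost | band-pass applied to UFM |
| HFEN_M | magnitude of per-axis high-passed (0.2 Hz, order 4) signals |

UFNM exploits the fact that a stationary sensor's magnitude is 1 g in any
orientation, so subtraction keeps movement components below the filter's
0.25 Hz edge that filtering would discard. FMpre and FMpost are *not*
interchangeable: the magnitude is nonlinear and does not commute with the
linear filter. Both are produced so the difference can be measured.

The default filter is a third-order Butterworth band-pass with corner
frequencies 0.25 and 2.5 Hz — the configuration most wearable devices
approximate, passing voluntary wrist movement while rejecting the DC
gravity term, slow orientation drift and high-frequency tremor/noise.

Numerical choices:

* **Phase handling.** Filters run causally by default (`mode = "causal"`),
  matching what on-device hardware does to the signal; a `zero_phase`
  forward–backward mode is available and documented as doubling the
  effective order. Activity metrics are computed per epoch, so the few
  hundred milliseconds of group delay in causal mode shift epoch contents
  negligibly at 60 s epochs.
* **Startup state.** Filter state is initialized to the steady-state
  response for the first sample, so a recording that begins at rest does
  not open with an artificial transient burst.
* **High orders.** Above order 8 the expanded polynomial coefficients of a
  band-pass are numerically useless, so the design switches to a
  closed-form zero-pole-gain Butterworth realized as cascaded biquads:
  every band-pass section receives the symmetric (1, 0, −1) zero template
  and unit gain at the band centre (this keeps intermediate signals of the
  cascade bounded), and the residual overall gain is fixed against the
  exact zero-pole-gain response. The cascade reproduces the direct design
  to ~1e-10 at order 3 and stays stable at order 30.

## Activity metrics and applicability

Seven metrics are implemented exactly as defined in the actigraphy
literature (`pim`, `zcm`, `tat`, `mad_epoch`, `enmo`, `hfen`,
`activity_index`). `compute_activity()` enforces which metric may run on
which dataset:

* PIM, ZCM and TAT cannot run on raw axial data: the per-axis gravity
  share depends on unknown device orientation and cannot be removed
  without filtering.
* ENMO requires UFM (the metric itself removes the 1 g offset);
  HFEN requires its specially conditioned magnitude; AI requires an axial
  triple (raw or filtered).
* MAD runs everywhere, including per raw axis, because it subtracts the
  epoch mean by construction.
* PIM on the zero-centred datasets (FXYZ, FMpost) integrates absolute
  values — the standard technical correction, applied automatically. PIM
  on UFM integrates the gravity-bearing magnitude as printed in the
  classical definition; an optional `baseline_subtract` flag removes the
  `n·T_s·1 g` epoch baseline, clipped at zero.

Decisions where definitions in the literature are silent:

* **ZCM crossing semantics**: strict sign-product rule; samples exactly on
  the threshold inherit the side of the previous strictly-off-threshold
  sample, so a flat touch of the level is not counted twice. No hysteresis
  is applied — the SD-adaptive threshold sits well above the noise floor,
  which is what debouncing would protect against.
* **TAT boundary**: strictly above the threshold; boundary samples do not
  count.
* **Simpson 3/8**: composite rule over groups of three intervals; when the
  epoch's interval count is not divisible by three the remaining one or
  two intervals are closed with the trapezoid rule. At 600 samples per
  epoch the tail contributes less than 0.4 % of the integral, which is why
  the two PIM rules agree almost perfectly.
* **Activity Index**: the default is the linear form
  `max(mean_m(σ_m² − σ̄²), 0)`. The original AI literature scales by a
  square root; a `variant = "sqrt"` flag provides it. Per-axis variances
  use the n−1 denominator.
* **Noise model**: `estimate_noise_variance()` takes the stillest 1 % of
  epochs by total axial variance and averages their per-axis variances.
  The quantile is configurable; 1 % of a half-day recording is minutes of
  genuinely still data, enough for a stable estimate but too little to be
  contaminated by movement.

## Thresholds

ZCM and TAT need a level. The package implements the adaptive rule: the
threshold equals the population SD of the *whole dataset* (not per epoch),
plus 1 g on UFM whose values ride on the gravity offset. The SD is
computed with denominator n; at the sample sizes involved (hundreds of
thousands of samples) the distinction from n−1 is far below every
tolerance in the package.

`threshold_sweep()` reproduces the level-sweep analysis: thresholds
`base + k·0.05 g` (from 1 g on UFM, 0 g elsewhere), with
`sweep_correlation_curve()` correlating every sweep member against
reference activity signals (ENMO and HFEN, the two metrics that can be
computed only one way) and against the SD-rule signal. On the default
synthetic cohort the curve rises steeply, peaks above 0.85 and decays, and
the SD rule lands within 0.02 of the grid maximum — the property that
justifies it as a universal default. A constant (degenerate) activity
signal yields a flagged `NA` correlation, never a silent zero.

Per-axis level-crossing runs use each axis's own SD (`axial_activity()`);
the choice is recorded in each output's threshold provenance.

## Axial combination

`combine_axial()` merges per-axis activity by sum, sum of squares or
VM3 = √(a_x² + a_y² + a_z²), checking metric, epoch grid and lineage
alignment. VM3 of activity values is *not* the activity of the vector
magnitude — integration and the Euclidean norm do not commute — which is
exactly why the package computes both sides for comparison.

## Correlation comparison

`pearson()` is the product-moment coefficient with classed errors on
constant input. `spectral_correlation()` correlates Welch PSD estimates
(Hann window, 50 % overlap, per-segment linear detrend, one-sided); the
segment length defaults to 256 epochs and is configurable — multi-hour
signals at 60 s epochs need a smaller segment (the multi-subject matrix
functions default to 128). `correlation_matrix()` computes the per-subject
pairwise matrix in either domain and averages identically located cells
across subjects into mean and SD matrices; undefined cells propagate as
missing with an effective-n count, never coerced to zero.

`default_catalog()` enumerates every permitted (metric, dataset,
combination, integration rule) signal definition: both PIM rules on the
four magnitude datasets, the five axial-capable metrics on FX/FY/FZ, MAD
additionally on the raw axes, ENMO, HFEN, AI on both triples, and the
three combination indicators for the four axial metrics — 57 definitions
by default, written to a plain CSV manifest so any run's enumeration can
be archived and reproduced exactly. The count is a property of this
package's default configuration, not a claim about any external catalog.

## The synthetic wrist-motion generator

Acceptance-style validation needs multi-hour triaxial recordings with
known structure. `generate_recording()` builds, per subject:

* a **gravity component** of norm exactly 1 g whose direction performs a
  random walk on the unit sphere (default 0.04 rad/√s — posture
  reorients by roughly ten degrees over a minute);
* **rest/active bouts** with exponential durations (means 110 s rest,
  50 s active), so minute epochs carry a graded active fraction;
* **movement bursts** during active bouts: a carrier that is 70 %
  narrowband Gaussian noise and 30 % oscillation at a per-bout frequency
  drawn from the lower half of the 0.3–2.0 Hz burst band (its magnitude
  harmonics then stay inside the 0.25–2.5 Hz analysis band), modulated by
  a lognormal envelope with a 1 s time constant (second-scale jerks and
  micro-pauses), directed along a per-subject dominant device axis with
  per-bout scatter, plus an isotropic broadband wobble;
* a **slow movement component** (0.05–0.2 Hz) during active bouts —
  posture and locomotion acceleration below the filter's band edge, which
  survives in UFM/UFNM but is removed from every filtered dataset;
* **sensor noise** (15 mg per axis) and **12-bit quantization** over ±8 g.

Several of these features are load-bearing for realism, and were chosen
because without them the synthetic data fails to behave like wrist data:
a noise-like carrier makes level-crossing counts grade smoothly with
intensity (Rice's crossing-rate law), which a pure tone does not; the
anatomical axis anisotropy is what makes a single well-chosen axis as
informative as the VM3 combination; the slow sub-band component is what
differentiates the unfiltered from the filtered preprocessing routes; and
the orientation drift is what separates the Activity Index (computed on
raw axes, orientation-sensitive) from the rotation-invariant magnitude
metrics. All scales are parameters of `scenario_params()`; the defaults
define the package's reference study conditions: 3 subjects × 12 h at
10 Hz (720 epochs per subject), with per-subject jitter of intensity and
bout durations, reproducible bit-for-bit from one master seed.

What the generator does **not** emulate: real activity-type structure
(gait cycles, typing, chewing), circadian and sleep architecture,
non-wear and device-removal artifacts, temperature drift and axis
miscalibration, and the heavy-tailed bout-duration laws of full multi-day
recordings (an optional Pareto mode exists but is not the default).
Passing tests therefore demonstrate that the *implementations* interact
the way the framework predicts on signals with realistic spectral and
bout structure — not that any particular clinical conclusion transfers.

## Validation choices worth recording

* **Rectification comparison.** The claim that full rectification of
  zero-mean filtered data approximately doubles ZCM/TAT while preserving
  the signal shape is checked on a purpose-built zero-mean band-limited
  series (carrier 0.25–1.0 Hz under a slowly drifting lognormal
  envelope). The carrier band is kept in the lower half of the analysis
  band deliberately: at 10 Hz sampling, a vigorous broadband carrier
  steps across the rectified signal's brief dips at sign changes, and the
  measured ratio drifts below 2 for reasons of discretization, not of the
  rectification identity itself.
* **Spectral validation of the generator.** The burst-band placement is
  asserted on the *filtered axial* signals (>80 % of active-bout power
  inside the configured band) plus an upper-edge check on FMpre (<10 %
  above 2.5 Hz). The magnitude operation itself relocates a substantial
  share of power to envelope (sub-band) frequencies — an intrinsic
  property of the nonlinearity, true of real data as well — so an in-band
  fraction computed on FMpre does not measure what the check intends.
* **Problem sizes.** Unit and property tests run on seconds-to-minutes of
  synthetic signal; the end-to-end checks use the 3 × 12 h reference
  cohort, which gives 720-epoch activity signals — enough for correlation
  estimates with sampling error well below the decision margins — while
  keeping the full suite fast.

## Known limitations

* The applicability matrix is enforced, not configurable; deliberately
  computing a disallowed combination requires calling the metric
  functions directly.
* `read_recording()` handles CSV and the package's own binary container;
  vendor-proprietary formats are out of scope.
* Frequency-domain comparison assumes equal-length activity signals on a
  shared epoch grid; no gap handling or resampling is provided.
* The Activity Index noise model assumes the noise floor is stationary
  across the recording.
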