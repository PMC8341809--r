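---
title: "Methods: quantifying upper-limb use from wrist-worn sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying upper-limb use from wrist-worn sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uluse)
```

## The measurement model

A wrist-worn IMU records, for each limb `i ∈ {l, r}`, a measurement signal
`M_i(t)` (tri-axial acceleration and angular velocity) over a finite epoch
`[0, T]`. Everything downstream is built from two derived signals:

* the binary **use** signal `u_i(t)`, 1 while the limb performs a
  voluntary, meaningful movement or posture, and
* the non-negative **instantaneous intensity** `μ_i(t) = u_i(t)·f_μ(M_i)(t)`,
  which by construction is zero outside use.

Both are idealisations: any detector realises them only approximately, with
a sensitivity/specificity trade-off discussed below. The windowed averages
over the trailing window `(t − D, t]`,

* average use `U_i(t; D) = (1/D)∫ u_i`,
* average intensity `I_i(t; D) = ∫μ_i / ∫u_i` (0 when `∫u_i = 0`),
* average activity `A_i(t; D) = U_i·I_i = (1/D)∫ μ_i`,

are the quantities that get visualised and summarised. `A = U·I` is an
identity, not an approximation: the package computes both sides from the
same discrete sums, and a regression test keeps their difference below
1e−9 on random inputs.

### Discretisation

Signals arrive sampled at `fs` Hz on a uniform grid with `t[1] = 0`.
Integrals use the rectangular (per-sample mean) rule, which is exact for
binary `u`. The window is the trailing `round(D·fs)` samples, covering the
half-open interval `(t − D, t]`; the first output falls exactly at
`t = D` and earlier times are dropped rather than padded, so a step signal
`u = 1` on `[0, 30 s]` with `D = 60 s` gives `U(60) = 0.5` exactly.
Non-uniform grids are rejected at construction; resampling is the reader's
job (`read_epoch(..., resample = "linear")` linearly interpolates files
with up to 1 % timing jitter). When a wear (validity) mask is present, any
window touching an invalid sample reports `U`, `I`, `A` as `NA` — a
partial window would silently bias all three.

The `I = 0/0 → 0` rule deserves emphasis: a window without any in-use
samples has *no defined* mean intensity, and the convention of reporting 0
(rather than `NA`) matches the construct — no use implies no intensity of
use — and keeps `A = U·I` an identity (`0 = 0·0`).

## Detectors

Two concrete use detectors and one intensity measure are shipped. They are
deliberately simple, fully parameterised, and deterministic.

**Activity counts** (`activity_counts()`): per axis, the acceleration (in
g) is demeaned and band-pass filtered (2nd-order Butterworth, 0.25–2.5 Hz,
applied forward-backward for zero phase; demeaning first keeps the
filter's edge transients from leaking the gravity DC level into the
counts). The vector magnitude of the filtered signal is dead-banded at
0.068 g, saturated at 2.13 g, quantised in 0.0164 g steps, and the steps
are summed per 1 s epoch. The constants mirror the conventions of
actigraph-style devices whose exact firmware chains are proprietary; this
chain is a documented, reproducible stand-in, and every constant is
exposed in `ac_params()`. Consequences worth knowing: a stationary sensor
yields exactly zero counts regardless of orientation; counts are invariant
to constant acceleration offsets; counts grow monotonically with
oscillation amplitude above the dead-band; postures are invisible.

**Thresholded-count use** (`threshold_use()`): `u = 1` iff counts exceed a
threshold (strict inequality; default 2 counts). Sensitive — essentially
any supra-threshold movement counts — but unspecific: passively
transported arms are flagged too. The threshold is a free parameter with
no canonical value; choose it against labelled data for a given device.

**Gross-movement score** (`gm_use()`): `u = 1` iff the smoothed gyro
magnitude exceeds 10 deg/s (movement) *and* the estimated forearm pitch
lies within ±30° of horizontal (a functional orientation band). Pitch is
estimated by a first-order complementary filter (coefficient 0.98 at the
gyro, i.e. a time constant of about 1 s at 50 Hz) fusing
accelerometer-derived inclination with the integrated gyro pitch rate; the
forearm long axis is the accelerometer x axis. The pitch window, the
threshold, the smoothing window (1 s) and the filter coefficient follow
the conventions of the gross-movement literature and are all configurable
(`gm_params()`); they are conventions, not measured facts. The detector is
highly specific — out-of-band movements are rejected no matter how
vigorous — but blind to postures and to in-band passive motion, and it
requires a gyroscope.

## Summary measures

### The percentile estimator

Both headline measures are percentiles of empirical distributions. The
package's estimator is the **nearest-rank inverse CDF**,
`sort(x)[ceiling(q/100·n)]`. The deciding property is that it commutes
with monotone increasing transforms: `P_q(g(x)) = g(P_q(x))`. That is what
makes the exact identities below hold with *finite* samples; any
interpolating estimator (e.g. the default `quantile()` type 7, available
as `method = "linear"`) breaks them by averaging adjacent order
statistics. A density-based route — estimate the joint density of `(U, I)`
or `(I_r, I_l)`, derive the product density, invert its CDF — defines the
same population quantities but adds an estimation layer with bandwidth
choices; the sample percentile is the direct estimator of the same thing
and is what the package computes throughout.

### Hq — overall activity

`hq(A, q = 90)` is the q-th percentile of the activity sample. It is
positively homogeneous (`Hq(cA) = c·Hq(A)`, exactly, by the commuting
property) and permutation invariant. Its behaviour is characterised on
uniform rectangles of the use–intensity plane: sampling
`U ~ Unif(0, 0.2), I ~ Unif(0, 10)` (short, weak use) gives `Hq ≈ 1.18`,
while `U ~ Unif(0.8, 1), I ~ Unif(40, 50)` (long, intense use) gives
`Hq ≈ 45.6`. Both have closed-form checks via the CDF of a product of
independent uniforms — for the first, `Hq = 2 z*` with `z*` solving
`z(1 − ln z) = 0.9`, about 1.175 — and the test suite verifies the
Monte-Carlo values against the numerically inverted CDF within three
standard errors at n = 200 000, a size chosen so the Monte-Carlo error
(≈ 0.003 for the first rectangle) is far below the 0.02 the checks allow.

### Rq — relative (bilateral) use

Over samples where at least one limb is active (`I_r + I_l > 0`; relative
use is meaningless when neither limb moves, so those samples are masked
out by `laterality_mask()`), let `q_r`, `q_l`, `q_rl` be the q-th
percentiles of `I_r`, `I_l`, `I_r·I_l`. Then

`Rq = q_rl / max(q_r², q_l²)`.

Exact finite-sample properties (all tested, all consequences of the
nearest-rank estimator):

* pure unimanual behaviour (`I_r·I_l ≡ 0`) → `Rq = 0`;
* symmetric bimanual behaviour (`I_r = I_l`) → `Rq = 1`;
* proportional behaviour `I_l = m·I_r` (or `I_l = I_r/m`), `0 ≤ m ≤ 1` →
  `Rq = m`;
* limb symmetry `Rq(I_r, I_l) = Rq(I_l, I_r)` and scale invariance
  `Rq(cI_r, cI_l) = Rq(I_r, I_l)`.

Because `Rq` is blind to direction, the dominant side is reported
separately as `sign(q_r − q_l)` (ties, within a 1e−12 relative tolerance,
give 0). Two numerical guards: percentile noise on diffuse point clouds
can push the ratio marginally above 1, so the value is clipped into
`[0, 1]` and the clipped amount is recorded (tests require it to stay
below 0.05 — larger clipping would signal estimator pathology, not
rounding); and if `q` is low enough that both marginal percentiles are 0
on sparse data, the ratio is undefined and `rq()` stops with advice to
raise `q` rather than returning a fabricated number.

`Rq` accepts `U` or `A` pairs in place of `I` pairs; the properties above
hold for any non-negative paired series.

## Laterality geometries

All views are pure, deterministic transforms of the masked pairs, computed
without a graphics device; plotting is a thin optional layer.

* **UI**: `(x, y) = (I, U)`, only `U > 0` windows; the left limb is
  mirrored (`x = −I`) into the second quadrant; iso-activity curves
  `U·I = c` annotate the plane.
* **BMMR**: `(x, y) = (ln(I_r/I_l), I_r + I_l)`. Pure unilateral samples
  map to `x = ±∞`; with clamping on (the default, following the plotting
  convention of the activity-count literature) they map to exactly ±7.
  The natural log matches that convention (±7 ≈ a 1100:1 ratio); the base
  is configurable. Both clamped and unclamped behaviours are exposed
  because analysis sometimes wants the honest infinity.
* **LIRI**: the identity embedding `(I_r, I_l)`.
* **ISID**: `(I_r − I_l, I_r + I_l)` — the LIRI plane rotated 45°
  counter-clockwise and scaled by √2 (the transform as printed omits the
  1/√2 of a pure rotation; the test verifies the rotation-matrix identity
  with the √2 factor). All points satisfy `y ≥ |x|`.
* **Reference curves** L1 (`I_l = c`), L2 (`I_r = c`), L3 (`I_l = c·I_r`),
  L4 (`I_l·I_r = c`) are generated in `(I_r, I_l)` space — each polyline
  point satisfies its defining equation to 1e−9 — then pushed through any
  view transform. L4 with `c = 0` degenerates to the axes and is rejected.
* **Workspace density**: a histogram density over positions gated by use
  (or its complement for the non-functional workspace), normalised to
  integrate to 1; the volume summary is the fraction of cells above a
  density quantile. A histogram (with grid resolution as the only knob)
  was chosen over KDE because no estimator is canonical here and the
  histogram keeps the normalisation exact. Note that a wrist IMU alone
  cannot produce positions; this estimator exists for richer measurement
  setups (motion capture, joint-space data) and is exercised on synthetic
  positions only.

## The synthetic-data module

The generators define the validation conditions for everything above.

`sample_uniform_region()` draws independent `(I, U)` points uniformly from
a rectangle — the generative model for the activity scenarios. Only the
two text-specified rectangles are shipped as canonical
(`scenario_region(1)` and `scenario_region(5)`); the intermediate
scenarios of that family have non-rectangular supports that are not
recoverable from a rectangle, so the package does not pretend to ship
them — compose regions if an approximation is wanted.

`laterality_pattern()` constructs `(I_r, I_l)` pairs realising the
archetypes *exactly* (unimanual: one series identically zero; symmetric:
`I_r = I_l`; scaled: `I_l = m·I_r`; banded: a diffuse rectangle), so the
exact `Rq` identities can be asserted as identities.

`simulate_imu_epoch()` synthesises two-limb IMU epochs from a bout
schedule. Each bout has a kind (`functional_move`, `functional_posture`,
`passive`, `rest`), an oscillation amplitude, and a forearm pitch; the
accelerometer reads gravity at that pitch plus a 1.5 Hz oscillation plus
white noise (0.05 m/s²), the gyro reads a proportional roll-rate
oscillation plus noise (0.5 deg/s). Ground truth is `u = 1` exactly during
functional bouts; `passive` bouts carry the *same* motion signature with
`u = 0`, which is what lets detector false-positive rates be measured.
One deliberate artifice: orientation changes between bouts are written
into the gyro pitch-rate channel as a one-sample impulse, so the
complementary filter tracks the scheduled pitch essentially immediately.
This makes the GM specificity test a test of the detector's logic rather
than of filter settling during an unobservable teleport. Default
conditions used by the tests: 50 Hz sampling, epochs of 60–300 s, bout
amplitudes of 1–3 m/s² (about 0.1–0.3 g, comfortably above the 0.068 g
dead-band).

What the simulator does **not** emulate: biomechanically realistic arm
trajectories, soft-tissue artefacts, sensor bias/drift and calibration
error, the ambiguity of real "meaningful use" (arm swing during gait,
fidgeting), multi-frequency movement content, and day-scale
non-stationarity. Passing tests therefore demonstrate that the detectors
and measures behave as specified *on their own constructs* — e.g. that
thresholded counts flag ≥ 95 % of scheduled functional movement and that
the GM score flags none of the out-of-band passive transport — not that
any particular sensitivity/specificity will be achieved on patient data.
Those properties are qualitative characterisations made testable by
construction, and real-world validation needs real labelled recordings.

All generators take one explicit seed per call and restore the caller's
RNG state, so identical seeds give bitwise-identical data and no global
state leaks.

## Defaults, in one place

| Parameter | Default | Where | Why |
|---|---|---|---|
| window `D` | 60 s | `ul_assess()`, `run_pipeline()` | standard reporting window for daily-life intensity averaging |
| percentile order `q` | 90 | `hq()`, `rq()` | high enough to summarise the active tail while robust to the top decile's noise |
| count band-pass | 0.25–2.5 Hz | `ac_params()` | voluntary arm-movement band; rejects gravity DC and tremor-band highs |
| dead-band / saturation / step | 0.068 g / 2.13 g / 0.0164 g | `ac_params()` | actigraph-style constants |
| count epoch | 1 s | `ac_params()` | matches the per-second intensity units used throughout |
| GM pitch window | ±30° | `gm_params()` | conventional functional-orientation band |
| GM movement threshold | 10 deg/s | `gm_params()` | separates deliberate movement from stillness/noise |
| complementary filter | 0.98 | `gm_params()` | ≈1 s fusion time constant at 50 Hz |
| use threshold (counts) | 2 | `threshold_use()` | free parameter; no canonical value exists |
| BMMR clamp | on, ±7, natural log | `bmmr_points()` | plotting convention for unilateral samples |

## Known limitations

* The detectors are intentionally minimal; no machine-learning use
  detector is provided.
* No inferential statistics (confidence intervals for Hq/Rq) — the
  measures are descriptive summaries here.
* Task recognition is out of scope: `task_label_signal()` exists so
  labelled data can be carried, but nothing constructs labels from
  measurements.
* `Hq` values computed with different intensity measures (`f_μ`) are not
  comparable across studies; always report the measure and its units.
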