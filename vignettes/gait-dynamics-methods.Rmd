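---
title: "Synthetic gait trials and nonlinear validation analyses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic gait trials and nonlinear validation analyses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdyn)
```

## Overview

`gaitdyn` is a pipeline for studying the stride-to-stride dynamics of human
overground walking recorded with body-worn inertial sensors. It has three
layers:

1. a **synthetic trial generator** that emulates the standard four-minute,
   200 Hz walking-trial export (48,000 rows, a `Time` column plus 320
   kinematic channels; 18 trials per subject over 2 days x 3 blocks x 3
   trials) with full ground truth;
2. **event detection and spatiotemporal extraction**: heel strikes and toe
   offs from the foot gyroscope channels, and the standard 26-column table
   of per-step and per-stride gait parameters;
3. three **nonlinear validation analyses**: continuous relative phase (CRP)
   between left and right segment pitch angles, the largest Lyapunov
   exponent (Wolf's algorithm with AMI/FNN embedding), and Bayesian
   estimation of the Hurst exponent of stride series under a fractional
   Gaussian noise model, with shuffled surrogates.

Every quantitative statement below is computed by the test suite or by
`scripts/acceptance.R`; none is taken on faith from this document.

## The synthetic walking model

The generator is a *contract-level* emulation: it reproduces the timing and
geometry structure that the downstream analyses consume, not a
physically-complete 3-D body model.

A trial is driven by a per-stride sequence. Stride times are
\[
s_k = \mu_T + \sigma_T z_k,
\]
where \(z_k\) is fractional Gaussian noise (fGn) with Hurst exponent \(H\);
stride lengths share the same driver through a configurable correlation
\(\rho\) (default 0.5): \(\ell_k = \mu_L + \sigma_L(\rho z_k +
\sqrt{1-\rho^2} z'_k)\). Defaults are \(\mu_T = 1.10\) s, \(\sigma_T =
0.022\) s (about a 2% coefficient of variation, typical of comfortable
adult walking), \(\mu_L = 1.35\) m, \(\sigma_L = 0.025\) m, and \(H = 0.9\)
(the strongly persistent regime reported for healthy stride series). The
defaults are study conditions, not tuning knobs: every analysis-facing test
either uses them or states its deviation explicitly.

Right heel strikes accumulate at \(h_{k+1} = h_k + s_k\); the left side is
offset by a fraction of each cycle (`phase_offset`, default 0.5 = perfect
anti-phase). A continuous stride counter \(\Psi(t)\), piecewise linear with
integer values at heel strikes, warps one-cycle templates onto the
irregular stride grid:

* **segment pitch angles** (thigh, shank, foot; both sides) are two-harmonic
  cosines of \(2\pi\Psi\) with segment-specific amplitudes and phase lags;
  the second harmonic is 10% of the first. Only the phase relations and
  event geometry matter downstream, so smooth, qualitatively gait-like
  waveforms suffice.
* the **foot gyroscope pitch rate** is identically zero during stance
  (cycle fraction up to the duty factor, default 0.62) and a half-sine
  burst during swing. The burst edges are the ground-truth toe-off and
  heel-strike instants — this is the event-detection signal.
* **foot positions** hold still during stance at the current placement and
  advance to the next placement along a smooth S-curve during swing, with
  alternating lateral offsets of half the step width (default 12 cm) and a
  parabolic-squared vertical lift; the **pelvis** advances through
  mid-stance positions at the realized gait speed with a small lateral sway
  (1 cm).

Additive Gaussian measurement noise (angles 0.2 deg, gyro 1 deg/s,
positions 1 mm, all scaled by `noise_scale`) and an optional horizontal
drift (a linear displacement added to all position channels, never vertical
ones — emulating the magnetometer-drift artifact of inertial motion
capture) complete the channel set. The remaining channels of the 321-column
layout are explicit zero-valued placeholders: the vendor's 320 channel
names are not public, so the synthetic export documents its own schema and
real exports are ingested through a `channel_map()`.

The generator returns a ground-truth record (true event times, stride
times/lengths, step width, injected \(H\), realized mean speed) enabling
parameter-recovery tests.

**What the generator does not emulate**: curved-track geometry and turning
mechanics, full-body joint kinematics, soft-tissue and sensor-fusion
artifacts, and any within-stance foot rotation. Passing recovery tests
therefore demonstrates correctness of the *extraction and analysis chain*,
not robustness to every pathology of real IMU data.

## Event detection and the 26-parameter table

Detection is a threshold-with-hysteresis state machine on the foot
pitch-rate channel: the channel is lightly smoothed (5-sample symmetric
moving average, which preserves the linear edge geometry), swing bursts
above half the (99th-percentile) amplitude are located, and bursts closer
than a 0.25 s refractory window are merged. Each burst edge is then refined
sub-sample: a secant is anchored on the edge at 10% of the amplitude —
where the signal-to-noise ratio is high, rather than at the noise-dominated
quiet floor — and extrapolated to its zero crossing. This removes the
half-sample quantization bias: on noise-free synthetic trials heel strikes
land within ~0.2 ms of truth (the suite asserts the one-sample contract),
and under the default sensor noise the median error stays below 1 ms, so
stride-interval series remain essentially uncontaminated for the Hurst
analysis. The detector is validated against ground truth; it does not
attempt to replicate any vendor's proprietary stance/swing firmware.
Partial cycles at the record edges are dropped.

The spatiotemporal table follows the standard 26-column schema (cadence,
step time, left/right step length, step width, stride length, stride time,
stance, swing, single/double support, the temporophasic percentages,
average speed, stride speeds, distance traveled), in that fixed order.
Conventions the source definitions leave open, fixed here:

* **step length** is the progression-axis component of the distance between
  successive opposite-foot heel centers (the field's usual convention);
  stride length is the horizontal Euclidean distance between same-foot heel
  centers.
* a **heel center** is the foot-sensor horizontal position sampled at the
  heel-strike time (markerless data offer nothing better).
* **step width** is the unsigned point-to-line distance from a heel center
  to the line joining the two flanking opposite-foot heel centers.
* **single support** (per right-referenced gait cycle) is the time the
  reference foot alone is on the ground — equal to the contralateral swing
  time, which the suite verifies independently via interval overlap;
  double support is the overlap of the two stance intervals.
* left and right series have ragged natural lengths (counts differ by at
  most one); table rows align by sample index and shorter series are padded
  with `NA`. Whole-trial scalars (average speed, distance) occupy one row.
* files are written at 6 significant digits so fixtures are byte-stable.

Internally everything is SI (meters, seconds); centimeter columns are
converted only at the table boundary. Positions use a right-handed frame
with x = progression, y = lateral, z = vertical.

## Continuous relative phase

Each gait cycle (right heel strike to the next) is cut from both signals,
time-normalized to 100 points by cubic spline (endpoints preserved; smooth
segments round-trip through resampling at interpolation accuracy), centered
with
\(x_c = x - \min x - (\max x - \min x)/2\),
and converted to a phase angle via the analytic signal
\(\zeta(t) = x_c(t) + i H\{x_c\}(t)\), with the Hilbert transform computed
in the frequency domain. The phase is evaluated **four-quadrant**
(`atan2`), not as a two-quadrant arctangent of \(H/x\): a two-quadrant
ratio cannot distinguish anti-phase from in-phase, which is the entire
point of the measure. Mirror padding (10 points per side, removed after the
transform) mitigates the finite-window edge bias on single-cycle segments;
on whole periodic records the unpadded transform is exact, which is how the
suite pins the phase of a pure cosine.

The relative phase is \(\Phi(t) = \varphi_{right}(t) - \varphi_{left}(t)\),
wrapped to \([0, 360)\): 0 deg is in-phase, 180 deg anti-phase. The
trial-level \(\bar\Phi\) pools all normalized points of all cycles and uses
the **circular** mean (an arithmetic mean is wrap-biased exactly where gait
lives, near 180 deg); dispersion is the circular SD. Whether one should
average within cycles first is not specified by the measure; pooling all
points is this package's documented convention, and for the anti-phase
contract the two differ negligibly. Trials with \(|\bar\Phi - 180| > 20\)
deg are flagged anomalous (configurable), mirroring the diagnostic use of
CRP for data-quality screening.

## Largest Lyapunov exponent

State space is reconstructed by delay embedding. The delay is the first
local minimum of the average mutual information (equiprobable 16-bin
estimator, in bits), with two robustness rules: a candidate minimum must
not be undercut within the next five lags (binned AMI curves ripple at the
0.01-bit level), and if no minimum exists within the scan range the first
drop below \(AMI(0)/e\) is used. On strictly noise-free periodic signals
the binned AMI is degenerate (the joint distribution is supported on a
curve and tie-breaking dominates), so the delay-selection tests use a
slightly noisy sinusoid; this is a property of binned estimators, not of
the implementation. The embedding dimension is chosen by false nearest
neighbors (Kennel ratio tolerance 15, Abarbanel loneliness tolerance 2 SD,
acceptance threshold 1%, Theiler exclusion); pairs whose added-coordinate
separation is at rounding level are true recurrences and are never counted
false.

The exponent follows Wolf's trajectory-following formulation: evolve the
fiducial point and its nearest admissible neighbor for a fixed number of
samples (default 3), accumulate \(\log(d'/d)\), and renormalize — when the
separation leaves the scale bounds (10% of the attractor extent by default)
or the neighbor runs out of record — by choosing a replacement point within
the bounds whose separation vector deviates least in angle (30 deg cap)
from the current one. \(\lambda_1 = \sum \log(d'/d) / T\) over the total
evolved time, reported in nats/s by default (bits/s by option; no base or
normalization is canonical in the gait literature, so both are exposed and
logged).

Numerical design choices worth knowing:

* the trajectory is centered and snapped to a grid at \(10^{-9}\) of the
  attractor extent before any search. Distances are mathematically
  invariant to translation and scaling, but the discrete neighbor choices
  would otherwise sit at the mercy of last-bit rounding; with the snap the
  suite asserts *identical* \(\lambda_1\) under translation and
  power-of-two scaling.
* neighbor selection uses strict-improvement margins (\(10^{-9}\)
  relative) so near-tie comparisons cannot flip between platforms.
* the Theiler window defaults to one mean period, estimated from the median
  spacing of local maxima of the (lightly smoothed) first coordinate.
* the evolution time should be a modest fraction of the mean period. The
  default (3 samples) suits densely sampled gait channels; the Lorenz
  cross-check uses 10 samples (0.2 time units at its dt = 0.02 sampling),
  about a quarter of the mean orbital period. Against an independent
  Benettin tangent-space oracle (~0.91 nats per time unit) the Wolf
  estimate agrees within the suite's 15% band; trajectory-following
  estimators are genuinely parameter-sensitive, which is why the
  cross-check exists.

Per-trial analysis (`trial_lle()`) selects delay and dimension on the first
5,000 samples and estimates the exponent on the full (optionally
decimated) series; segment pitch angles are the analysis channels.

## Hurst exponent of stride series

Stride-time and stride-length series are modeled as stationary Gaussian
fGn: autocorrelation
\(\rho(k) = \tfrac12(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})\),
which the generator also uses for exact simulation by circulant (spectral)
embedding — the embedding eigenvalues are non-negative on \(H \in (0,1]\),
so simulated series have exactly the target autocovariance, and recovery
tests are meaningful.

The estimator is Bayesian: uniform prior on \(H\) over (0,1), the mean
profiled out by generalized least squares, the scale marginalized
analytically under a noninformative prior, leaving
\[
p(H \mid x) \propto |R_H|^{-1/2}\,(\mathbf{1}'R_H^{-1}\mathbf{1})^{-1/2}\,
S(H)^{-(n-1)/2},
\]
with \(S(H)\) the GLS residual sum of squares. All three quadratic forms
and \(\log|R_H|\) come from one \(O(n^2)\) Levinson-Durbin sweep per grid
point (C++, forward-vectorized, verified against dense solves), which is
the right cost regime for stride series of a few hundred to a few thousand
samples — the short-series regime this estimator family is chosen for. The
posterior is evaluated on a coarse 0.01 grid over (0,1) plus a 0.001-step
refinement around the mode (the posterior SD at n >= 64 is far wider than
the coarse step, so no mass is lost and the refinement restores full
resolution where it matters); the point estimate is the posterior median
with a central 95% credible interval. Standardizing the input first makes
affine invariance exact.

Calibration, all computed by the suite: mean estimates over 100 replicates
of n = 2048 are 0.50 +/- 0.03 on white noise, 0.90 +/- 0.03 on fGn(0.9),
0.10 +/- 0.05 on fGn(0.1); bias is below 0.05 at n = 1024 across
H in {0.3, 0.5, 0.7, 0.9}. Shuffled surrogates (exact permutations,
deterministic under a seed) return persistent series to ~0.5, confirming
that estimated long-range correlation reflects temporal ordering. At ~218
strides per four-minute trial the single-trial sampling SD is ~0.04-0.05,
so end-to-end recovery is asserted on a small average of trials. Left and
right stride series are analyzed separately and pooled (in heel-strike
order); the left-side series of the generator is a half-cycle interpolation
and is slightly smoothed relative to the driver, which is visible as a
mildly higher H — another reason both sides are reported.

## The cohort pipeline

`run_validation()` simulates (or ingests) a cohort, extracts events and
parameters, runs the requested analyses, and writes per-trial and
per-subject/day CSVs plus a run log recording the package version, seeds,
and every generator and analysis parameter in effect. Per-trial seeds are
derived deterministically from the master seed (Lehmer-style mixing kept
within exact double arithmetic), so identical configurations produce
byte-identical summaries. Subjects present on one day only are processed
without failure. `consistency_summary()` reports between-day absolute
differences and the ratio of between-subject variance to within-subject
(between-day) variance — deliberately descriptive, not an ICC with
significance machinery, since the claim it supports is qualitative:
subject-level metrics should be far more stable across days than across
subjects.

## Problem sizes used by the tests

The suite exercises full-size (240 s, 48,000-sample) trials where the
structural claims require them, and 45-90 s trials elsewhere; Hurst
calibration sweeps use 100 replicates of n = 2048 (the acceptance script
repeats these from scratch), recovery tables 20 replicates at n = 1024, and
the Lorenz cross-check ~13,500 points. These sizes were chosen so the whole
suite completes in a few minutes on a single core while keeping every
Monte-Carlo tolerance comfortably wider than its sampling error.

## Known limitations

* The generator's left-foot placement interpolates between right-foot
  placements, so left stride series are smoothed versions of the driver;
  treat left-side H as qualitative.
* The event detector expects a quiet stance floor on the gyro channel; it
  is not a drop-in detector for raw field IMU data without tuning the
  threshold fractions.
* Wolf's \(\lambda_1\) is parameter-sensitive by nature; values are
  comparable only under identical embedding and evolution settings, which
  the run log records.
* CRP assumes approximately sinusoidal, single-dominant-frequency segment
  angles within a cycle; heavily multi-modal waveforms would need the
  per-cycle normalization revisited.
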