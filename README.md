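# gaitdyn

Synthetic IMU walking trials and nonlinear dynamics of human gait, in R.

## The problem

Healthy human walking is variable in a structured way: stride-to-stride
fluctuations are not white noise but carry long-range correlations, the
left and right legs are locked in anti-phase, and segment trajectories
diverge slowly and reproducibly across gait cycles. Those three properties
— temporal structure, inter-limb coordination, and local dynamic stability
— are the standard nonlinear validation battery for large gait recordings,
and they are exactly what this package computes. It is written for movement
scientists who work with long overground-walking records from body-worn
inertial sensors (4-minute trials at 200 Hz, 18 trials per subject over
two days) and who need a tested, reproducible implementation of that
battery, plus a synthetic data generator with known ground truth to
validate every step of the chain without access to a motion-capture
laboratory.

## What it computes

**Spatiotemporal extraction.** Heel strikes and toe offs are detected from
the foot gyroscope pitch-rate channel (threshold with hysteresis,
sub-sample edge refinement), and the standard 26-column table of gait
parameters is derived per trial: cadence, step time, step/stride
length, step width, stance/swing/support times, their percent-of-gait-cycle
forms, speeds, and distance traveled.

**Continuous relative phase (CRP).** Per gait cycle, both segment pitch
angles are time-normalized to 100 points, centered
(`x - min x - (max x - min x)/2`), converted to phase angles
`phi(t) = atan2(H{x}(t), x(t))` via the Hilbert analytic signal, and
differenced: `Phi(t) = phi_right(t) - phi_left(t)`. `Phi = 0°` is
in-phase, `180°` anti-phase; the trial mean is circular.

**Largest Lyapunov exponent.** Delay embedding with the delay at the first
minimum of the average mutual information and the dimension from false
nearest neighbors, then Wolf's trajectory-following algorithm:
`lambda1 = (1/T) * sum log(d'/d)` over evolution segments with
angle-constrained neighbor replacement, in nats/s.

**Hurst exponent of stride series.** Stride times and lengths are modeled
as fractional Gaussian noise with autocorrelation
`rho(k) = (|k+1|^2H - 2|k|^2H + |k-1|^2H)/2`; a Bayesian estimator
(uniform prior on H, mean profiled, scale marginalized, exact Gaussian
likelihood via Levinson–Durbin Toeplitz solves) returns the posterior
median and credible interval. `H = 0.5` is white noise, `H > 0.5`
persistent ("pink-noise-like"), `H < 0.5` anti-persistent. Shuffled
surrogates confirm that detected persistence comes from temporal ordering.

**Synthetic cohorts.** `simulate_trial()` builds trials with fGn-driven
stride sequences, anti-phase segment waveforms, planted foot/pelvis
positions, sensor noise and optional horizontal drift — and returns the
ground truth, so recovery is testable. `run_validation()` and
`consistency_summary()` run the whole battery over a cohort and report
between-day test-retest consistency.

## Worked example

```r
library(gaitdyn)

sim    <- simulate_trial(trial_config(seed = 42))   # standard 240 s trial
trial  <- sim$trial
events <- detect_gait_events(trial)
tab    <- compute_gait_parameters(events, trial)

print(trial)
#> <raw_trial> (unkeyed): 48000 samples x 320 channels @ 200 Hz
print(events)
#> <gait_events> left: 213 HS / 213 TO; right: 213 HS / 213 TO

summ <- summarize_trial(tab)
summ[c(1, 10, 23), c("parameter", "n", "mean", "sd")]
#>                parameter   n    mean      sd
#> 1    cadence (steps/min) 425 106.729 1.41634
#> 10 right stride time (s) 212   1.124 0.01485
#> 23   average speed (m/s)   1   1.248 0.00000

trial_crp(trial, "thigh", events = events)
#> <crp_result> Phi_bar = 180.24 deg (circ SD 8.83), 212 cycles

st <- tab[["right stride time (s)"]]
estimate_hurst(st[!is.na(st)])
#> <hurst_result> H_hat = 0.812 [0.711, 0.921] (n = 212)
estimate_hurst(shuffle_surrogate(st[!is.na(st)], seed = 1))$H_hat
#> [1] 0.543
```

Reading the output: the trial has the standard export shape (48,000
samples, 200 Hz, 320 channels plus time) and 213 detected strides per
foot, matching a 240 s walk at ~1.12 s per stride. The left-right thigh
relative phase sits at 180° — anti-phase, as legs must. The stride-time
series, injected with Hurst exponent 0.9, is estimated at 0.81 from a
single 212-stride trial (single-trial sampling spread is roughly ±0.05);
shuffling the same series collapses the estimate to ~0.5, showing the
persistence lives in the ordering, not the amplitude distribution.

A cohort-level run, including the anomaly flags and between-day
consistency summaries, is one call:

```r
rep <- run_validation(validation_config(n_subjects = 3, seed = 1), out_dir = "out")
consistency_summary(rep)$variance_ratio
```

A thin command-line front end over the same functions is provided in
`inst/scripts/gaitpipe.R`
(`simulate | extract | crp | lle | hurst | validate`).

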