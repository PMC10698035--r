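#' Default generator configuration
#'
#' Study conditions for a standard synthetic overground-walking trial:
#' 4 minutes at 200 Hz (48,000 samples), self-paced gait emulated with a
#' mean stride time of 1.10 s and mean stride length of 1.35 m, stride
#' fluctuations driven by fractional Gaussian noise with a persistent
#' Hurst exponent (0.9) as seen in healthy stride series, perfect left-right
#' anti-phase (offset 0.5 cycle), a 12 cm step width, and a 62% duty factor
#' (stance fraction of the gait cycle).
#'
#' @param ... Overrides for any default field.
#' @return Named list of generator parameters.
#' @export
trial_config <- function(...) {
  cfg <- list(
    duration_s = 240,          # trial length (s)
    fs = 200,                  # sampling rate (Hz)
    mean_stride_time = 1.10,   # s
    stride_time_sd = 0.022,    # s (~2% CV)
    stride_time_H = 0.9,       # Hurst exponent of stride-time fluctuations
    mean_stride_length = 1.35, # m
    stride_length_sd = 0.025,  # m
    length_time_cor = 0.5,     # shared-driver correlation, lengths vs times
    step_width = 0.12,         # m
    phase_offset = 0.5,        # left-right offset, fraction of gait cycle
    duty_factor = 0.62,        # stance fraction of the cycle
    thigh_amp = 20, shank_amp = 30, foot_amp = 25,  # pitch amplitudes (deg)
    harmonic2_frac = 0.10,     # relative 2nd-harmonic content of pitch angles
    gyro_peak = 300,           # swing-phase foot pitch rate peak (deg/s)
    swing_height = 0.05,       # foot lift during swing (m)
    pelvis_sway = 0.01,        # lateral pelvis oscillation amplitude (m)
    pelvis_height = 1.0,       # m
    noise_scale = 1,           # multiplies per-channel measurement noise
    angle_noise_sd = 0.2,      # deg
    gyro_noise_sd = 1.0,       # deg/s
    pos_noise_sd = 0.001,      # m
    drift_rate = 0,            # horizontal drift speed (m/s)
    drift_azimuth_deg = 90,    # drift direction (0 = progression, 90 = lateral)
    full_channels = TRUE,      # pad to the standard 320-channel layout
    seed = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    gd_stop(paste0("unknown generator parameters: ", paste(bad, collapse = ", ")),
            "gaitdyn_domain_error")
  }
  modifyList(cfg, over)
}

# Smooth swing progression profile: 0 -> 1 with zero end velocities.
scurve <- function(u) u - sin(2 * pi * u) / (2 * pi)

#' Simulate one synthetic walking trial with ground truth
#'
#' Builds left and right thigh/shank/foot pitch angles by warping smooth
#' one-cycle waveform templates onto stride intervals drawn as mean + fGn
#' fluctuations; the left side is offset by `phase_offset` of a cycle
#' (0.5 = perfect anti-phase). Foot positions advance by per-stride lengths
#' with alternating lateral offsets giving the target step width, the foot
#' gyroscope pitch-rate channel is zero in stance and a half-sine burst in
#' swing (the event-detection signal), and the pelvis advances at the
#' instantaneous gait speed. Optional additive measurement noise and
#' horizontal-plane drift. Returns the trial together with a ground-truth
#' record (true events, stride times/lengths, injected Hurst exponent, ...)
#' enabling parameter-recovery tests.
#'
#' @param config A [trial_config()].
#' @param key Optional [trial_key()] attached to the trial.
#' @return List with elements `trial` (a [raw_trial()]) and `truth`.
#' @export
simulate_trial <- function(config = trial_config(), key = NULL) {
  cfg <- config
  n <- cfg$duration_s * cfg$fs
  if (abs(n - round(n)) > 1e-9) {
    gd_stop("duration * fs must be an integer sample count", "gaitdyn_domain_error")
  }
  n <- as.integer(round(n))
  if (cfg$mean_stride_time < 0.4) {
    gd_stop("mean stride time must be >= 0.4 s", "gaitdyn_domain_error")
  }
  df <- cfg$duty_factor
  if (df <= 0 || df >= 1) gd_stop("duty factor must lie in (0,1)", "gaitdyn_domain_error")

  seed <- if (is.null(cfg$seed)) NULL else as.integer(cfg$seed)
  # number of strides: cover [-1 stride, duration + 2 strides]
  K <- ceiling((cfg$duration_s + 4 * cfg$mean_stride_time) / (0.8 * cfg$mean_stride_time)) + 2L

  # shared fGn driver: stride times and lengths correlated through z1
  z1 <- simulate_fgn(K, cfg$stride_time_H, seed = if (is.null(seed)) NULL else derive_seed(seed, 1))
  z2 <- simulate_fgn(K, cfg$stride_time_H, seed = if (is.null(seed)) NULL else derive_seed(seed, 2))
  rho <- cfg$length_time_cor
  s_times <- cfg$mean_stride_time + cfg$stride_time_sd * z1
  s_lens <- cfg$mean_stride_length +
    cfg$stride_length_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  if (any(s_times <= 0) || any(s_lens <= 0)) {
    gd_stop("parameter combination produced non-positive stride times/lengths",
            "gaitdyn_generation_error")
  }

  # right heel-strike knots; stride k runs h[k] -> h[k+1] with duration s_times[k]
  h_r <- numeric(K + 1)
  h_r[1] <- -s_times[1]
  for (k in 1:K) h_r[k + 1] <- h_r[k] + s_times[k]
  if (h_r[K + 1] < cfg$duration_s + 2 * cfg$mean_stride_time) {
    gd_stop("internal: stride cover too short", "gaitdyn_internal_error")
  }
  po <- cfg$phase_offset
  h_l <- h_r[1:K] + po * s_times            # left HS within stride k
  h_l <- c(h_l, h_l[K] + s_times[K])        # extend one knot

  # foot placements (progression axis, m): right stance k at X_r[k]
  X_r <- numeric(K + 1)
  X_r[1] <- 0
  for (k in 1:K) X_r[k + 1] <- X_r[k] + s_lens[k]
  X_l <- X_r[1:K] + po * (X_r[2:(K + 1)] - X_r[1:K])
  X_l <- c(X_l, X_l[K] + s_lens[K])

  tt <- seq(0, by = 1 / cfg$fs, length.out = n)

  # continuous stride counter Psi (integer at each heel strike)
  psi_r <- approx(h_r, seq_along(h_r) - 1, xout = tt)$y
  psi_l <- approx(h_l, seq_along(h_l) - 1, xout = tt)$y
  if (anyNA(psi_r) || anyNA(psi_l)) {
    gd_stop("internal: phase cover incomplete", "gaitdyn_internal_error")
  }

  a2 <- cfg$harmonic2_frac
  pitch <- function(psi, A, p1, p2) {
    A * (cos(2 * pi * psi + p1) + a2 * cos(4 * pi * psi + p2))
  }
  seg_phase_lags <- list(thigh = c(0, -1.2), shank = c(-0.8, -2.0), foot = c(-1.6, -2.6))

  foot_kin <- function(psi, X, lat) {
    k <- floor(psi)
    u <- psi - k
    x0 <- X[k + 1]
    x1 <- X[k + 2]
    swing <- u > df
    v <- pmax((u - df) / (1 - df), 0)
    x <- x0 + ifelse(swing, (x1 - x0) * scurve(v), 0)
    z <- ifelse(swing, cfg$swing_height * sin(pi * v)^2, 0)
    gyro <- ifelse(swing, cfg$gyro_peak * sin(pi * v), 0)
    list(x = x, y = rep(lat, length(psi)), z = z, gyro = gyro)
  }
  fr <- foot_kin(psi_r, X_r, -cfg$step_width / 2)
  fl <- foot_kin(psi_l, X_l, +cfg$step_width / 2)

  # pelvis: linear progression through mid-stance positions, small sway
  pel_knots_x <- (X_r[1:K] + X_r[2:(K + 1)]) / 2
  pel_x <- approx(h_r[1:K] + 0.5 * s_times, pel_knots_x, xout = tt, rule = 2)$y
  pel_y <- cfg$pelvis_sway * sin(4 * pi * psi_r)
  pel_z <- rep(cfg$pelvis_height, n)

  # measurement noise
  noise <- function(sd, idx) {
    s <- cfg$noise_scale * sd
    if (s <= 0) return(0)
    with_seed(if (is.null(seed)) NULL else derive_seed(seed, 100 + idx), rnorm(n, 0, s))
  }

  # horizontal drift: displaces all positions, never vertical channels
  az <- cfg$drift_azimuth_deg * pi / 180
  drift_x <- cfg$drift_rate * tt * cos(az)
  drift_y <- cfg$drift_rate * tt * sin(az)

  ch <- list()
  ch[["right_thigh_pitch_deg"]] <- pitch(psi_r, cfg$thigh_amp, seg_phase_lags$thigh[1], seg_phase_lags$thigh[2]) + noise(cfg$angle_noise_sd, 1)
  ch[["left_thigh_pitch_deg"]]  <- pitch(psi_l, cfg$thigh_amp, seg_phase_lags$thigh[1], seg_phase_lags$thigh[2]) + noise(cfg$angle_noise_sd, 2)
  ch[["right_shank_pitch_deg"]] <- pitch(psi_r, cfg$shank_amp, seg_phase_lags$shank[1], seg_phase_lags$shank[2]) + noise(cfg$angle_noise_sd, 3)
  ch[["left_shank_pitch_deg"]]  <- pitch(psi_l, cfg$shank_amp, seg_phase_lags$shank[1], seg_phase_lags$shank[2]) + noise(cfg$angle_noise_sd, 4)
  ch[["right_foot_pitch_deg"]]  <- pitch(psi_r, cfg$foot_amp, seg_phase_lags$foot[1], seg_phase_lags$foot[2]) + noise(cfg$angle_noise_sd, 5)
  ch[["left_foot_pitch_deg"]]   <- pitch(psi_l, cfg$foot_amp, seg_phase_lags$foot[1], seg_phase_lags$foot[2]) + noise(cfg$angle_noise_sd, 6)
  ch[["right_foot_gyro_pitch_dps"]] <- fr$gyro + noise(cfg$gyro_noise_sd, 7)
  ch[["left_foot_gyro_pitch_dps"]]  <- fl$gyro + noise(cfg$gyro_noise_sd, 8)
  ch[["right_foot_pos_x_m"]] <- fr$x + drift_x + noise(cfg$pos_noise_sd, 9)
  ch[["right_foot_pos_y_m"]] <- fr$y + drift_y + noise(cfg$pos_noise_sd, 10)
  ch[["right_foot_pos_z_m"]] <- fr$z + noise(cfg$pos_noise_sd, 11)
  ch[["left_foot_pos_x_m"]] <- fl$x + drift_x + noise(cfg$pos_noise_sd, 12)
  ch[["left_foot_pos_y_m"]] <- fl$y + drift_y + noise(cfg$pos_noise_sd, 13)
  ch[["left_foot_pos_z_m"]] <- fl$z + noise(cfg$pos_noise_sd, 14)
  ch[["pelvis_pos_x_m"]] <- pel_x + drift_x + noise(cfg$pos_noise_sd, 15)
  ch[["pelvis_pos_y_m"]] <- pel_y + drift_y + noise(cfg$pos_noise_sd, 16)
  ch[["pelvis_pos_z_m"]] <- pel_z + noise(cfg$pos_noise_sd, 17)

  named <- do.call(cbind, ch)
  colnames(named) <- names(ch)
  if (isTRUE(cfg$full_channels)) {
    n_aux <- 320L - ncol(named)
    aux <- matrix(0, n, n_aux,
                  dimnames = list(NULL, sprintf("aux_channel_%03d", seq_len(n_aux))))
    channels <- cbind(named, aux)
  } else {
    channels <- named
  }
  trial <- raw_trial(time_ms = tt * 1000, channels = channels, key = key)

  in_win <- function(x) x[x >= 0 & x < cfg$duration_s]
  hs_r <- h_r[h_r >= 0 & h_r < cfg$duration_s]
  hs_l <- h_l[h_l >= 0 & h_l < cfg$duration_s]
  to_r <- (h_r[1:K] + df * s_times)
  to_l <- (h_l[1:K] + df * (h_l[2:(K + 1)] - h_l[1:K]))
  # strides fully inside the recorded window, per foot
  win_strides <- function(h, lens) {
    k <- which(h >= 0 & h < cfg$duration_s)
    k <- k[k < length(h)]
    k <- k[h[k + 1] < cfg$duration_s]
    list(times = h[k + 1] - h[k], lengths = lens[k])
  }
  ws_r <- win_strides(h_r, c(s_lens, NA))
  ws_l <- win_strides(h_l, c(diff(X_l), NA))
  truth <- list(
    heel_strikes = list(left = in_win(hs_l), right = in_win(hs_r)),
    toe_offs = list(left = in_win(to_l), right = in_win(to_r)),
    stride_times = list(left = ws_l$times, right = ws_r$times),
    stride_lengths = list(left = ws_l$lengths, right = ws_r$lengths),
    hs_knots = list(left = h_l, right = h_r),
    placements_x = list(left = X_l, right = X_r),
    step_width = cfg$step_width,
    phase_offset = po,
    stride_time_H = cfg$stride_time_H,
    duty_factor = df,
    mean_speed = (pel_x[n] - pel_x[1]) / (tt[n] - tt[1]),  # realized, drift-free
    drift_rate = cfg$drift_rate,
    config = cfg
  )
  list(trial = trial, truth = truth)
}

#' Simulate a full synthetic subject (18-trial standard protocol)
#'
#' Writes one CSV per trial, named by the canonical token, for 2 days x
#' 3 blocks x 3 trials (or the subset of `days` given). Per-trial seeds are
#' derived deterministically from the subject-level seed.
#'
#' @param subject Subject number.
#' @param out_dir Output directory (created if needed).
#' @param config A [trial_config()]; `seed` acts as the subject master seed.
#' @param days Days to simulate (default both).
#' @param group Group number.
#' @return Invisibly, a named list of truth records keyed by trial token.
#' @export
simulate_subject <- function(subject, out_dir, config = trial_config(),
                             days = 1:2, group = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truths <- list()
  for (key in subject_trial_keys(subject, group, days)) {
    cfg <- config
    cfg$seed <- derive_seed(if (is.null(config$seed)) 0L else config$seed,
                            subject, key$day, key$block, key$trial)
    sim <- simulate_trial(cfg, key = key)
    tok <- format(key)
    write_raw_trial(sim$trial, file.path(out_dir, paste0(tok, ".csv")))
    truths[[tok]] <- sim$truth
  }
  invisible(truths)
}
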