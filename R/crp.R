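#' Center an angle series about zero
#'
#' Applies `x - min(x) - (max(x) - min(x))/2`, so that the series' extrema
#' sit symmetrically about 0 and the derived segment phase angles orient
#' around 0 degrees.
#'
#' @param x Numeric series (length >= 2).
#' @return Centered series.
#' @examples
#' center_series(c(0, 2))    # -1, 1
#' center_series(c(1, 3, 5)) # -2, 0, 2
#' @export
center_series <- function(x) {
  if (length(x) < 2) gd_stop("series too short to center", "gaitdyn_domain_error")
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("constant series: centered to all zeros")
    return(rep(0, length(x)))
  }
  x - rng[1] - diff(rng) / 2
}

#' Time-normalize one gait-cycle segment to n points
#'
#' Cubic-spline interpolation onto `n` evenly spaced points; endpoints are
#' preserved exactly, affine inputs are reproduced exactly, and smooth
#' (band-limited) segments round-trip through resampling at interpolation
#' accuracy.
#'
#' @param x Numeric series (length >= 2).
#' @param n Target length (default 100).
#' @return Numeric vector of length `n`.
#' @export
normalize_cycle <- function(x, n = 100) {
  if (n < 2) gd_stop("n must be >= 2", "gaitdyn_domain_error")
  if (length(x) < 2) gd_stop("segment too short", "gaitdyn_domain_error")
  if (length(x) == 2) {
    return(approx(seq_along(x), x, xout = seq(1, 2, length.out = n))$y)
  }
  stats::spline(seq_along(x), x, xout = seq(1, length(x), length.out = n),
                method = "fmm")$y
}

# Analytic signal z = x + i * H{x} via frequency-domain construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Mirror-pad, transform, strip: mitigates the finite-window edge bias of the
# Hilbert transform on short cycle segments.
analytic_signal_padded <- function(x, pad = 10) {
  n <- length(x)
  pad <- min(pad, n - 1)
  if (pad > 0) {
    y <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    z <- analytic_signal(y)
    z[(pad + 1):(pad + n)]
  } else {
    analytic_signal(x)
  }
}

#' Segment phase angle via the Hilbert analytic signal
#'
#' Centers the series, forms the analytic signal
#' `zeta(t) = x_centered(t) + i H(t)` by Hilbert transform, and returns the
#' segment phase angle `phi(t) = arctan(H(t) / x_centered(t))` evaluated
#' four-quadrant, in degrees in (-180, 180]. For a pure sinusoid the phase
#' advances monotonically by 360 degrees per period.
#'
#' @param x Angle series (length >= 8, non-constant).
#' @param pad Mirror-padding width for edge-effect mitigation (default 10).
#' @return A `phase_series` list: `x`, `x_centered`, `hilbert_part`, `phi`
#'   (degrees).
#' @export
segment_phase <- function(x, pad = 10) {
  if (length(x) < 8) gd_stop("series too short for phase analysis", "gaitdyn_domain_error")
  if (diff(range(x)) == 0) gd_stop("constant series has no phase", "gaitdyn_domain_error")
  xc <- center_series(x)
  z <- analytic_signal_padded(xc, pad)
  h <- Im(z)
  phi <- atan2(h, xc) * 180 / pi
  phi[phi <= -180] <- phi[phi <= -180] + 360
  structure(list(x = x, x_centered = xc, hilbert_part = h, phi = phi),
            class = "phase_series")
}

#' Continuous relative phase between right and left segment angles
#'
#' For each complete gait cycle (heel strike to next heel strike of the
#' reference right foot) both signals are cut over the same window,
#' time-normalized to 100 points, centered, and converted to segment phase
#' angles; the continuous relative phase is
#' `Phi(t) = phi_right(t) - phi_left(t)`, wrapped to \[0, 360). 0 degrees is
#' in-phase, 180 degrees anti-phase. The trial-level mean is the circular
#' mean of all points of all cycles.
#'
#' @param right,left Angle series on the same uniform time base.
#' @param cycles A [gait_events()] (right-foot heel strikes delimit cycles)
#'   or a numeric vector of cycle-start times (s).
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample (s), default 0.
#' @param n_points Points per normalized cycle (default 100).
#' @param flag_threshold Trials with `|Phi_bar - 180| >` this value (degrees)
#'   are flagged anomalous (default 20).
#' @return A `crp_result`: `phi_mean` (circular mean, degrees in \[0,360)),
#'   `phi_sd` (circular SD), `cycles` (n_cycles x n_points matrix of Phi),
#'   `n_cycles`, `anomalous`.
#' @export
crp_series <- function(right, left, cycles, fs, t0 = 0, n_points = 100,
                       flag_threshold = 20) {
  if (length(right) != length(left)) {
    gd_stop("right and left series must have equal length", "gaitdyn_domain_error")
  }
  starts <- if (inherits(cycles, "gait_events")) cycles$right$heel_strikes else cycles
  idx <- round((starts - t0) * fs) + 1
  idx <- idx[idx >= 1 & idx <= length(right)]
  if (length(idx) < 2) gd_stop("no complete gait cycles", "gaitdyn_insufficient_data")
  mats <- vector("list", length(idx) - 1)
  for (k in seq_len(length(idx) - 1)) {
    sel <- idx[k]:idx[k + 1]
    if (length(sel) < 8) next
    pr <- segment_phase(normalize_cycle(right[sel], n_points))
    pl <- segment_phase(normalize_cycle(left[sel], n_points))
    mats[[k]] <- wrap360(pr$phi - pl$phi)
  }
  mats <- mats[!vapply(mats, is.null, TRUE)]
  if (!length(mats)) gd_stop("no complete gait cycles", "gaitdyn_insufficient_data")
  phi <- do.call(rbind, mats)
  phi_mean <- circ_mean_deg(phi)
  structure(list(phi_mean = phi_mean, phi_sd = circ_sd_deg(phi),
                 cycles = phi, n_cycles = nrow(phi),
                 anomalous = abs(wrap180(phi_mean - 180)) > flag_threshold),
            class = "crp_result")
}

#' @export
print.crp_result <- function(x, ...) {
  cat(sprintf("<crp_result> Phi_bar = %.2f deg (circ SD %.2f), %d cycles%s\n",
              x$phi_mean, x$phi_sd, x$n_cycles,
              if (x$anomalous) " [ANOMALOUS]" else ""))
  invisible(x)
}

#' Trial-level CRP for a named segment pair
#'
#' Convenience wrapper: resolves the left/right pitch channels of a segment
#' (`"thigh"`, `"shank"` or `"foot"`), detects cycles if not supplied, and
#' runs [crp_series()].
#'
#' @param trial A [raw_trial()].
#' @param segment One of `"thigh"`, `"shank"`, `"foot"`.
#' @param events Optional [gait_events()]; detected if missing.
#' @param map A [channel_map()].
#' @param ... Passed to [crp_series()].
#' @return A `crp_result`.
#' @export
trial_crp <- function(trial, segment = c("thigh", "shank", "foot"),
                      events = NULL, map = default_channel_map(), ...) {
  segment <- match.arg(segment)
  if (is.null(events)) events <- detect_gait_events(trial, map)
  r <- trial_channel(trial, paste0("right_", segment, "_pitch"), map)
  l <- trial_channel(trial, paste0("left_", segment, "_pitch"), map)
  crp_series(r, l, events, fs = sampling_rate(trial),
             t0 = trial$time_ms[1] / 1000, ...)
}
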