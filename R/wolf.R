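#' Largest Lyapunov exponent by Wolf's trajectory-following algorithm
#'
#' Follows a reference trajectory through the reconstructed state space:
#' the nearest neighbor of the current point (outside the Theiler window,
#' within the scale bounds) is evolved alongside it for `evolve` samples,
#' the log of the ratio of final to initial separation is accumulated, and
#' a replacement neighbor is sought (minimal angular deviation from the
#' current separation vector, then minimal distance) whenever the
#' separation leaves the scale bounds. The exponent is
#' \deqn{\lambda_1 = \frac{1}{T} \sum \log\frac{d_t'}{d_t}}
#' with `T` the total evolved time. A smaller `lambda1` indicates higher
#' predictability (less divergence); scale and translation of the
#' trajectory leave it unchanged.
#'
#' @param trajectory State matrix (rows = time-ordered states), e.g. from
#'   [delay_embed()]; at least 500 rows.
#' @param fs Sampling rate of the underlying series (Hz); `lambda1` is
#'   reported per second.
#' @param evolve Evolution time between renormalizations, in samples
#'   (default 3).
#' @param dmax_frac Replacement threshold as a fraction of the attractor
#'   extent (default 0.1).
#' @param dmin_frac Noise floor as a fraction of extent (default 1e-8).
#' @param max_angle Maximum angular deviation (degrees) accepted when
#'   replacing a neighbor (default 30).
#' @param theiler Theiler exclusion window in samples; default one mean
#'   period, estimated from the median spacing of local maxima of the
#'   first coordinate.
#' @param base Logarithm base: `"nats"` (natural, default) or `"bits"`.
#' @return An `lle_result`: `lambda1`, `units`, `n_segments`,
#'   `replacements`, `diagnostics` (per-segment `d0`, `d1`, `dt_s`), and the
#'   parameters used.
#' @export
wolf_lle <- function(trajectory, fs, evolve = 3, dmax_frac = 0.1,
                     dmin_frac = 1e-8, max_angle = 30, theiler = NULL,
                     base = c("nats", "bits")) {
  base <- match.arg(base)
  X <- as.matrix(trajectory)
  n <- nrow(X)
  if (n < 500) gd_stop("trajectory too short (< 500 points)", "gaitdyn_domain_error")
  X <- sweep(X, 2, colMeans(X))  # distances are translation-invariant
  extent <- sqrt(sum((apply(X, 2, max) - apply(X, 2, min))^2))
  if (extent <= 0) gd_stop("degenerate trajectory", "gaitdyn_domain_error")
  # snap coordinates to a grid far below any dynamical scale, so that the
  # discrete neighbor choices (and hence lambda1) are invariant under
  # translation/scaling of the input rather than at the mercy of rounding
  q <- extent * 1e-9
  X <- round(X / q) * q
  dmax <- dmax_frac * extent
  dmin <- dmin_frac * extent
  if (is.null(theiler)) theiler <- mean_period_samples(X[, 1])
  theiler <- as.integer(theiler)

  i <- 1L
  nb <- .wolf_neighbor(X, i, rep(0, ncol(X)), theiler, dmin, dmax, max_angle,
                       n - evolve)
  if (is.na(nb$index)) {
    gd_stop("no valid neighbors within scale bounds", "gaitdyn_insufficient_data")
  }
  j <- nb$index
  S <- 0; Ttot <- 0; nseg <- 0L; nrep <- 0L
  d0s <- d1s <- numeric(0)
  while (i + evolve <= n && j + evolve <= n) {
    d0 <- sqrt(sum((X[i, ] - X[j, ])^2))
    i2 <- i + evolve; j2 <- j + evolve
    d1 <- sqrt(sum((X[i2, ] - X[j2, ])^2))
    if (d0 > dmin && d1 > 0) {
      S <- S + log(d1 / d0)
      Ttot <- Ttot + evolve / fs
      nseg <- nseg + 1L
      d0s <- c(d0s, d0); d1s <- c(d1s, d1)
    }
    i <- i2
    if (i + evolve > n) break
    if (d1 > dmax || d1 <= dmin || j2 + evolve > n) {
      # renormalize when the separation leaves the scale bounds (or the
      # neighbor runs out of record): replace the neighbor with a point
      # close to the fiducial whose separation vector deviates least in
      # angle from the current one
      dir <- X[j2, ] - X[i, ]
      nb <- .wolf_neighbor(X, i, dir, theiler, dmin, dmax, max_angle, n - evolve)
      if (is.na(nb$index)) break
      if (nb$index != j2) nrep <- nrep + 1L
      j <- nb$index
    } else {
      j <- j2
    }
  }
  if (nseg == 0) gd_stop("no usable evolution segments", "gaitdyn_insufficient_data")
  lambda <- S / Ttot
  if (base == "bits") lambda <- lambda / log(2)
  structure(list(lambda1 = lambda,
                 units = paste0(base, "/s"),
                 n_segments = nseg, replacements = nrep,
                 diagnostics = data.frame(d0 = d0s, d1 = d1s,
                                          dt_s = evolve / fs),
                 params = list(evolve = evolve, dmax_frac = dmax_frac,
                               dmin_frac = dmin_frac, max_angle = max_angle,
                               theiler = theiler, fs = fs)),
            class = "lle_result")
}

#' @export
print.lle_result <- function(x, ...) {
  cat(sprintf("<lle_result> lambda1 = %.4f %s (%d segments, %d replacements)\n",
              x$lambda1, x$units, x$n_segments, x$replacements))
  invisible(x)
}

#' Largest Lyapunov exponent of one trial channel
#'
#' Full pipeline for a segment pitch-angle channel: AMI first-minimum
#' delay, FNN embedding dimension, delay embedding, Wolf exponent.
#'
#' @param trial A [raw_trial()].
#' @param role Channel role (default `"right_thigh_pitch"`).
#' @param map A [channel_map()].
#' @param max_lag AMI scan range (default 2 s worth of samples).
#' @param max_dim FNN scan range (default 8).
#' @param downsample Integer decimation factor applied before analysis
#'   (default 1 = none).
#' @param select_n Samples used for the AMI/FNN parameter selection stage
#'   (default 5000); the exponent itself uses the full series.
#' @param ... Passed to [wolf_lle()].
#' @return An `lle_result` with `tau` and `dim` recorded in `$embedding`.
#' @export
trial_lle <- function(trial, role = "right_thigh_pitch",
                      map = default_channel_map(), max_lag = NULL,
                      max_dim = 8, downsample = 1, select_n = 5000, ...) {
  x <- trial_channel(trial, role, map)
  fs <- sampling_rate(trial)
  if (downsample > 1) {
    x <- x[seq(1, length(x), by = downsample)]
    fs <- fs / downsample
  }
  if (is.null(max_lag)) max_lag <- as.integer(round(2 * fs))
  xsel <- x[seq_len(min(length(x), select_n))]
  ami <- average_mutual_information(xsel, max_lag)
  fnn <- false_nearest_neighbors(xsel, ami$tau, max_dim)
  dim <- if (is.na(fnn$dim)) max_dim else fnn$dim
  res <- wolf_lle(delay_embed(x, dim, ami$tau), fs, ...)
  res$embedding <- list(tau = ami$tau, dim = dim)
  res
}


# Mean oscillation period (samples) from the median spacing of local maxima
# of a lightly smoothed copy of the series.
mean_period_samples <- function(x) {
  n <- length(x)
  k <- 5L
  xs <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  pk <- which(diff(sign(diff(xs))) < 0) + 1L
  if (length(pk) >= 3) {
    max(1L, as.integer(round(stats::median(diff(pk)))))
  } else {
    max(1L, n %/% 100L)
  }
}
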