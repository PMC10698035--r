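#' Fractional Gaussian noise autocorrelation
#'
#' Closed-form autocorrelation of stationary fGn with Hurst exponent `H`:
#' \deqn{\rho(k) = \tfrac12 (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}).}
#' `H = 0.5` gives white noise (`rho(k) = 0` for `k >= 1`); `H > 0.5` gives
#' persistent, power-law decaying correlations ("pink-noise-like");
#' `H < 0.5` anti-persistent (negative lag-1 correlation).
#'
#' @param H Hurst exponent in (0, 1].
#' @param k Integer lag(s), `k >= 0`.
#' @return Autocorrelation value(s) in \[-0.5, 1\].
#' @examples
#' fgn_autocorrelation(0.5, 1)   # 0: white noise
#' fgn_autocorrelation(0.9, 1)   # ~0.741: strong persistence
#' @export
fgn_autocorrelation <- function(H, k) {
  if (length(H) != 1 || is.na(H) || H <= 0 || H > 1) {
    gd_stop("H must lie in (0, 1]", "gaitdyn_domain_error")
  }
  if (any(k < 0) || any(k != floor(k))) {
    gd_stop("lags must be non-negative integers", "gaitdyn_domain_error")
  }
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

#' Simulate fractional Gaussian noise
#'
#' Exact simulation of stationary fGn by circulant (spectral) embedding of
#' the closed-form autocovariance (Davies-Harte). The circulant eigenvalues
#' are non-negative for all `H` in (0, 1], so the construction is exact: the
#' returned series is Gaussian with autocovariance `sigma^2 *
#' fgn_autocorrelation(H, k)`.
#'
#' @param n Series length (`n >= 2`).
#' @param H Hurst exponent in (0, 1).
#' @param sigma Standard deviation (> 0).
#' @param mean Series mean.
#' @param seed Optional integer seed; the same seed reproduces the series
#'   exactly and the caller's RNG state is left untouched.
#' @return Numeric vector of length `n`.
#' @export
simulate_fgn <- function(n, H, sigma = 1, mean = 0, seed = NULL) {
  if (n < 2) gd_stop("n must be >= 2", "gaitdyn_domain_error")
  if (sigma <= 0) gd_stop("sigma must be positive", "gaitdyn_domain_error")
  if (H <= 0 || H >= 1) {
    # H = 1 is a degenerate (perfectly correlated) boundary; simulation
    # supports the open interval.
    gd_stop("H must lie in (0, 1) for simulation", "gaitdyn_domain_error")
  }
  r <- fgn_autocorrelation(H, 0:n)
  first_row <- c(r[1:n], r[n + 1], r[n:2])  # circulant of size 2n
  lambda <- Re(stats::fft(first_row))
  if (any(lambda < -1e-8 * max(lambda))) {
    gd_stop("circulant embedding produced negative eigenvalues",
            "gaitdyn_internal_error")
  }
  lambda[lambda < 0] <- 0
  m <- 2L * n
  x <- with_seed(seed, {
    v0 <- rnorm(1)
    vn <- rnorm(1)
    a <- rnorm(n - 1)
    b <- rnorm(n - 1)
    w <- complex(real = c(v0, a / sqrt(2), vn, rev(a) / sqrt(2)),
                 imaginary = c(0, b / sqrt(2), 0, -rev(b) / sqrt(2)))
    z <- stats::fft(sqrt(lambda) * w)
    Re(z[1:n]) / sqrt(m)
  })
  mean + sigma * x
}

#' Random shuffle surrogate
#'
#' Returns a uniformly random permutation of `x` (the amplitude
#' distribution is preserved exactly; temporal ordering is destroyed).
#' Estimating the Hurst exponent of shuffled series should return values
#' near 0.5, confirming that estimated long-range correlation arises from
#' ordering rather than the marginal distribution.
#'
#' @param x Numeric vector (`length >= 2`).
#' @param seed Optional integer seed for a deterministic permutation.
#' @return Permuted copy of `x`.
#' @export
shuffle_surrogate <- function(x, seed = NULL) {
  if (length(x) < 2) gd_stop("need at least 2 values", "gaitdyn_domain_error")
  with_seed(seed, x[sample.int(length(x))])
}
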