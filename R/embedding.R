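#' Average mutual information and the first-minimum delay
#'
#' Estimates the mutual information (bits) between `x(t)` and `x(t + lag)`
#' for lags `0..max_lag`, using equiprobable (rank-based) binning. The
#' recommended embedding delay is the first local minimum of the AMI curve;
#' if no local minimum exists within `max_lag`, the first lag at which the
#' AMI drops below `AMI(0)/e` is used instead.
#'
#' @param x Numeric series (length >= 10 * max_lag recommended).
#' @param max_lag Largest lag scanned.
#' @param bins Number of equiprobable bins (default 16).
#' @return List: `lags`, `ami` (bits), `tau` (selected delay),
#'   `rule` ("first_minimum" or "one_over_e").
#' @export
average_mutual_information <- function(x, max_lag, bins = 16) {
  n <- length(x)
  if (diff(range(x)) == 0) gd_stop("constant series", "gaitdyn_domain_error")
  if (max_lag < 1 || n <= max_lag + 1) {
    gd_stop("series too short for requested max_lag", "gaitdyn_domain_error")
  }
  # equiprobable binning via ranks
  b <- ceiling(rank(x, ties.method = "first") / (n / bins))
  b <- pmin(pmax(b, 1L), bins)
  ami <- numeric(max_lag + 1)
  for (lag in 0:max_lag) {
    u <- b[1:(n - lag)]
    v <- b[(1 + lag):n]
    joint <- table(u, v) / length(u)
    pu <- rowSums(joint); pv <- colSums(joint)
    nz <- joint > 0
    ami[lag + 1] <- sum(joint[nz] * log2(joint[nz] / outer(pu, pv)[nz]))
  }
  # first local minimum, made robust to estimator ripple: a lag qualifies
  # only if no smaller AMI value occurs within the next `min_window` lags
  min_window <- 5L
  tau <- NA_integer_; rule <- "first_minimum"
  for (lag in 1:(max_lag - 1)) {
    ahead <- ami[(lag + 2):min(lag + 1 + min_window, max_lag + 1)]
    if (ami[lag + 1] < ami[lag] && all(ami[lag + 1] <= ahead)) {
      tau <- lag; break
    }
  }
  if (is.na(tau)) {
    rule <- "one_over_e"
    drop <- which(ami <= ami[1] / exp(1))
    tau <- if (length(drop)) drop[1] - 1L else max_lag
    if (tau < 1) tau <- 1L
  }
  list(lags = 0:max_lag, ami = ami, tau = as.integer(tau), rule = rule)
}

#' Delay embedding of a scalar series
#'
#' Builds the trajectory matrix of delay vectors
#' `(x_t, x_{t+tau}, ..., x_{t+(dim-1) tau})`; rows are the
#' `n - (dim - 1) * tau` reconstructed states.
#'
#' @param x Numeric series.
#' @param dim Embedding dimension (>= 1).
#' @param tau Delay in samples (>= 1).
#' @return Matrix with `dim` columns.
#' @export
delay_embed <- function(x, dim, tau) {
  n <- length(x)
  if (dim < 1 || tau < 1) gd_stop("dim and tau must be >= 1", "gaitdyn_domain_error")
  m <- n - (dim - 1) * tau
  if (m < 2) gd_stop("series too short for this embedding", "gaitdyn_domain_error")
  out <- matrix(NA_real_, m, dim)
  for (d in seq_len(dim)) out[, d] <- x[(1 + (d - 1) * tau):(m + (d - 1) * tau)]
  out
}

#' False nearest neighbors and the minimal embedding dimension
#'
#' Kennel's criterion: for each embedding dimension `d`, find every state's
#' nearest neighbor (excluding temporal neighbors within the Theiler
#' window); the pair is a false neighbor if adding the (d+1)-th delay
#' coordinate stretches the distance by more than `rtol` times the d-dim
#' distance, or beyond `atol` times the series' standard deviation. The
#' selected dimension is the smallest whose false-neighbor fraction falls
#' below `threshold`.
#'
#' @param x Numeric series.
#' @param tau Embedding delay (samples).
#' @param max_dim Largest dimension scanned (default 8).
#' @param rtol Distance-ratio tolerance (default 15).
#' @param atol Loneliness tolerance in SD units (default 2).
#' @param threshold False-neighbor fraction below which a dimension is
#'   accepted (default 0.01).
#' @param theiler Theiler exclusion window in samples (default `tau`).
#' @return List: `dims`, `fnn_fraction`, `dim` (selected).
#' @export
false_nearest_neighbors <- function(x, tau, max_dim = 8, rtol = 15, atol = 2,
                                    threshold = 0.01, theiler = tau) {
  n <- length(x)
  if (n - max_dim * tau < 10) {
    gd_stop("series too short for requested max_dim", "gaitdyn_domain_error")
  }
  sdx <- sd(x)
  frac <- rep(NA_real_, max_dim)
  sel <- NA_integer_
  for (d in seq_len(max_dim)) {
    m <- n - d * tau  # states for which the (d+1)-th coordinate exists
    emb <- delay_embed(x, d, tau)[1:m, , drop = FALSE]
    nn <- .nn_all(emb, as.integer(theiler))
    j <- nn$index
    dist_d <- nn$dist
    ok <- !is.na(j) & dist_d > 0
    extra <- abs(x[(1:m) + d * tau] - x[j + d * tau])
    # numerical floor: pairs whose added-coordinate separation is at
    # rounding level (exact recurrences) are true neighbors by construction
    eps <- 1e-8 * sdx
    # second clause: Abarbanel's loneliness test, R_{d+1} > atol * sd(x)
    false_nb <- ((extra[ok] / dist_d[ok] > rtol) & (extra[ok] > eps)) |
      (sqrt(dist_d[ok]^2 + extra[ok]^2) / sdx > atol)
    frac[d] <- mean(false_nb)
    if (is.na(sel) && frac[d] < threshold) {
      sel <- d
      break
    }
  }
  list(dims = seq_len(max_dim), fnn_fraction = frac, dim = sel)
}
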