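# Internal helpers shared across modules.

#' Wrap angles (degrees) into [0, 360)
#' @noRd
wrap360 <- function(a) ((a %% 360) + 360) %% 360

#' Wrap angles (degrees) into (-180, 180]
#' @noRd
wrap180 <- function(a) {
  w <- wrap360(a)
  ifelse(w > 180, w - 360, w)
}

#' Circular mean of angles in degrees, result in [0, 360)
#' @noRd
circ_mean_deg <- function(a) {
  r <- a * pi / 180
  wrap360(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Circular standard deviation (degrees)
#' @noRd
circ_sd_deg <- function(a) {
  r <- a * pi / 180
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  R <- min(max(R, .Machine$double.eps), 1)
  sqrt(-2 * log(R)) * 180 / pi
}

#' Derive a deterministic 31-bit substream seed from a master seed
#'
#' Simple Lehmer-style integer hash; keeps every derived seed between 1 and
#' 2^31 - 2 so it is a valid R RNG seed.
#' @noRd
derive_seed <- function(master, ...) {
  ks <- c(master, ...)
  h <- 17
  for (k in ks) {
    # Lehmer-style mixing; 48271 * 2^31 < 2^53 keeps arithmetic exact
    h <- (h * 48271 + as.numeric(k) + 1) %% 2147483647
    h <- (h * 48271) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

#' Evaluate an expression under a local RNG seed, restoring RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' Stop with a gaitdyn-classed error
#' @noRd
gd_stop <- function(msg, class) {
  stop(structure(class = c(class, "gaitdyn_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
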