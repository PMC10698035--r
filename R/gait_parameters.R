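# Interval helpers (closed-open intervals on the time axis).
overlap_len <- function(a0, a1, b0, b1) {
  pmax(0, pmin(a1, b1) - pmax(a0, b0))
}

# Unsigned distance (m) from point p to the infinite line through a and b
# in the horizontal plane.
point_line_distance <- function(p, a, b) {
  ab <- b - a
  nrm <- sqrt(sum(ab^2))
  if (nrm < .Machine$double.eps) return(sqrt(sum((p - a)^2)))
  abs(ab[1] * (a[2] - p[2]) - ab[2] * (a[1] - p[1])) / nrm
}

#' Compute the 26 spatiotemporal gait parameters of a trial
#'
#' Applies the standard per-step/per-stride definitions to detected gait
#' events and foot/pelvis positions: step length is the progression-axis
#' distance from one heel strike to the next heel strike of the opposite
#' foot; stride length the horizontal distance between consecutive heel
#' strikes of the same foot; step width the lateral distance from a heel
#' center to the line joining the two flanking heel centers of the opposite
#' foot; stance runs heel strike to toe off of the same footfall and swing
#' toe off to the next heel strike; single support is the time the
#' reference foot alone is on the ground within its gait cycle and double
#' support the time both feet are; temporophasic values are normalized to
#' stride time; cadence is steps per minute; average speed is pelvis path
#' length over trial time and distance traveled the pelvis horizontal path
#' length; stride speed is stride length over stride time.
#'
#' Heel centers are the foot-sensor horizontal positions sampled at
#' heel-strike times. Gait cycles are referenced to right heel strikes for
#' the support-time columns.
#'
#' @param events A [gait_events()].
#' @param trial The [raw_trial()] the events came from.
#' @param map A [channel_map()].
#' @return A [gait_parameter_table()].
#' @export
compute_gait_parameters <- function(events, trial, map = default_channel_map()) {
  tt <- trial$time_ms / 1000
  t0 <- tt[1]; t1 <- tt[length(tt)]
  for (side in c("left", "right")) {
    ev <- events[[side]]
    if (min(ev$toe_offs[1], ev$heel_strikes[1]) < t0 - 1e-9 ||
        max(ev$heel_strikes) > t1 + 1e-9) {
      gd_stop("event times fall outside the trial time range", "gaitdyn_invariant_error")
    }
  }
  fs <- sampling_rate(trial)
  pos_at <- function(side, times) {
    ix <- pmin(pmax(round((times - t0) * fs) + 1, 1), length(tt))
    cbind(x = trial_channel(trial, paste0(side, "_foot_pos_x"), map)[ix],
          y = trial_channel(trial, paste0(side, "_foot_pos_y"), map)[ix])
  }

  per_foot <- list()
  for (side in c("left", "right")) {
    hs <- events[[side]]$heel_strikes
    to <- events[[side]]$toe_offs
    K <- length(hs) - 1
    stride_time <- diff(hs)
    stance <- swing <- rep(NA_real_, K)
    for (k in seq_len(K)) {
      tk <- to[to > hs[k] & to < hs[k + 1]]
      if (length(tk) == 1) {
        stance[k] <- tk - hs[k]
        swing[k] <- hs[k + 1] - tk
      }
    }
    heel <- pos_at(side, hs)
    stride_len <- sqrt(diff(heel[, "x"])^2 + diff(heel[, "y"])^2)
    per_foot[[side]] <- list(hs = hs, to = to, stride_time = stride_time,
                             stance = stance, swing = swing, heel = heel,
                             stride_len = stride_len)
  }

  # merged step sequence (all heel strikes in time order)
  all_hs <- c(per_foot$left$hs, per_foot$right$hs)
  all_side <- c(rep("left", length(per_foot$left$hs)),
                rep("right", length(per_foot$right$hs)))
  o <- order(all_hs)
  all_hs <- all_hs[o]; all_side <- all_side[o]
  if (any(all_side[-1] == all_side[-length(all_side)])) {
    gd_stop("left and right heel strikes do not interleave", "gaitdyn_invariant_error")
  }
  step_time <- diff(all_hs)
  cadence <- 60 / step_time

  # step length: progression-axis distance between successive opposite-foot
  # heel centers, attributed to the foot that lands
  heel_of <- function(side, t) {
    pf <- per_foot[[side]]
    pf$heel[match(t, pf$hs), , drop = FALSE]
  }
  step_len <- list(left = numeric(0), right = numeric(0))
  for (i in seq_along(step_time)) {
    a <- heel_of(all_side[i], all_hs[i])
    b <- heel_of(all_side[i + 1], all_hs[i + 1])
    step_len[[all_side[i + 1]]] <- c(step_len[[all_side[i + 1]]],
                                     abs(b[1, "x"] - a[1, "x"]))
  }

  # step width: heel center vs line joining the flanking opposite-foot strikes
  step_width <- list(left = numeric(0), right = numeric(0))
  for (side in c("left", "right")) {
    other <- if (side == "left") "right" else "left"
    hs <- per_foot[[side]]$hs
    ohs <- per_foot[[other]]$hs
    for (k in seq_along(hs)) {
      j <- findInterval(hs[k], ohs)
      if (j >= 1 && j < length(ohs)) {
        w <- point_line_distance(per_foot[[side]]$heel[k, ],
                                 per_foot[[other]]$heel[j, ],
                                 per_foot[[other]]$heel[j + 1, ])
        step_width[[side]] <- c(step_width[[side]], w)
      }
    }
  }

  # support times per right-referenced gait cycle
  r <- per_foot$right; l <- per_foot$left
  Kr <- length(r$hs) - 1
  single <- double <- rep(NA_real_, Kr)
  l_stance0 <- l$hs[-length(l$hs)]
  l_stance1 <- rep(NA_real_, length(l_stance0))
  for (k in seq_along(l_stance0)) {
    tk <- l$to[l$to > l$hs[k] & l$to < l$hs[k + 1]]
    if (length(tk) == 1) l_stance1[k] <- tk
  }
  ok <- !is.na(l_stance1)
  l_stance0 <- l_stance0[ok]; l_stance1 <- l_stance1[ok]
  for (k in seq_len(Kr)) {
    if (is.na(r$stance[k])) next
    rs0 <- r$hs[k]; rs1 <- rs0 + r$stance[k]
    dbl <- sum(overlap_len(l_stance0, l_stance1, rs0, rs1))
    double[k] <- dbl
    single[k] <- r$stance[k] - dbl  # right foot alone = contralateral swing
  }

  # whole-trial pelvis path
  px <- trial_channel(trial, "pelvis_pos_x", map)
  py <- trial_channel(trial, "pelvis_pos_y", map)
  dist_m <- sum(sqrt(diff(px)^2 + diff(py)^2))
  avg_speed <- dist_m / (t1 - t0)

  series <- list(
    "cadence (steps/min)" = cadence,
    "step time (s)" = step_time,
    "left step length (cm)" = 100 * step_len$left,
    "right step length (cm)" = 100 * step_len$right,
    "left step width (cm)" = 100 * step_width$left,
    "right step width (cm)" = 100 * step_width$right,
    "left stride length (cm)" = 100 * per_foot$left$stride_len,
    "right stride length (cm)" = 100 * per_foot$right$stride_len,
    "left stride time (s)" = per_foot$left$stride_time,
    "right stride time (s)" = per_foot$right$stride_time,
    "left stance time (s)" = per_foot$left$stance,
    "right stance time (s)" = per_foot$right$stance,
    "left swing time (s)" = per_foot$left$swing,
    "right swing time (s)" = per_foot$right$swing,
    "single support time (s)" = single,
    "double support time (s)" = double,
    "left pct stance (%GC)" = 100 * per_foot$left$stance / per_foot$left$stride_time,
    "right pct stance (%GC)" = 100 * per_foot$right$stance / per_foot$right$stride_time,
    "left pct swing (%GC)" = 100 * per_foot$left$swing / per_foot$left$stride_time,
    "right pct swing (%GC)" = 100 * per_foot$right$swing / per_foot$right$stride_time,
    "pct single (%GC)" = 100 * single / per_foot$right$stride_time,
    "pct double (%GC)" = 100 * double / per_foot$right$stride_time,
    "average speed (m/s)" = avg_speed,
    "left stride speed (m/s)" = per_foot$left$stride_len / per_foot$left$stride_time,
    "right stride speed (m/s)" = per_foot$right$stride_len / per_foot$right$stride_time,
    "distance traveled (m)" = dist_m
  )
  gait_parameter_table(series, key = trial$key)
}

#' Per-trial summary of a gait parameter table
#'
#' @param table A [gait_parameter_table()].
#' @return A `data.frame` with one row per parameter: `parameter`, `n`,
#'   `mean`, `sd`, and `all_missing` (flagged, not fatal).
#' @export
summarize_trial <- function(table) {
  if (!inherits(table, "gait_table") || nrow(table) == 0) {
    gd_stop("empty gait parameter table", "gaitdyn_invariant_error")
  }
  rows <- lapply(colnames(table), function(cn) {
    v <- table[[cn]]
    v <- v[!is.na(v)]
    data.frame(parameter = cn, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else if (length(v)) 0 else NA_real_,
               all_missing = length(v) == 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "key") <- attr(table, "key")
  out
}
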