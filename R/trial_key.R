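#' Trial identity keys
#'
#' Every walking trial is identified by a five-field key: subject, study
#' group, day (1-2), block within session (1-3) and trial within block
#' (1-3), rendered as the canonical token `S###_G##_D##_B##_T##`
#' (e.g. `"S001_G01_D01_B01_T01"`). The standard protocol yields 18 trials
#' per subject: 2 days x 3 blocks x 3 trials.
#'
#' @param subject,group Positive integers.
#' @param day Integer 1 or 2.
#' @param block Integer 1, 2 or 3.
#' @param trial Integer 1, 2 or 3.
#' @return An object of class `trial_key`.
#' @examples
#' k <- trial_key(1, 1, 1, 1, 1)
#' format(k)
#' parse_trial_id("S017_G01_D02_B03_T02")
#' @export
trial_key <- function(subject, group = 1L, day = 1L, block = 1L, trial = 1L) {
  k <- list(subject = as.integer(subject), group = as.integer(group),
            day = as.integer(day), block = as.integer(block),
            trial = as.integer(trial))
  validate_trial_key(k)
  structure(k, class = "trial_key")
}

validate_trial_key <- function(k) {
  for (f in c("subject", "group", "day", "block", "trial")) {
    v <- k[[f]]
    if (length(v) != 1 || is.na(v) || v < 1) {
      gd_stop(sprintf("trial key field '%s' must be a positive integer", f),
              "gaitdyn_parse_error")
    }
  }
  if (k$day > 2) gd_stop("day must be 1 or 2", "gaitdyn_parse_error")
  if (k$block > 3) gd_stop("block must be 1, 2 or 3", "gaitdyn_parse_error")
  if (k$trial > 3) gd_stop("trial must be 1, 2 or 3", "gaitdyn_parse_error")
  invisible(k)
}

#' @export
format.trial_key <- function(x, ...) {
  sprintf("S%03d_G%02d_D%02d_B%02d_T%02d",
          x$subject, x$group, x$day, x$block, x$trial)
}

#' @export
print.trial_key <- function(x, ...) {
  cat("<trial_key>", format(x), "\n")
  invisible(x)
}

#' @export
`==.trial_key` <- function(e1, e2) {
  identical(format(e1), format(e2))
}

#' Parse a canonical trial identifier token
#'
#' @param token A string of the form `S###_G##_D##_B##_T##`.
#' @return A [trial_key()].
#' @export
parse_trial_id <- function(token) {
  if (length(token) != 1 || !nzchar(token)) {
    gd_stop("trial id token must be a non-empty string", "gaitdyn_parse_error")
  }
  parts <- strsplit(token, "_", fixed = TRUE)[[1]]
  prefixes <- c("S", "G", "D", "B", "T")
  fields <- c("subject", "group", "day", "block", "trial")
  if (length(parts) != 5) {
    gd_stop(sprintf(
      "malformed trial id '%s': expected 5 segments S/G/D/B/T, got %d",
      token, length(parts)), "gaitdyn_parse_error")
  }
  vals <- integer(5)
  for (i in seq_len(5)) {
    seg <- parts[i]
    if (!grepl(paste0("^", prefixes[i], "[0-9]+$"), seg)) {
      gd_stop(sprintf("malformed trial id '%s': segment '%s' (%s) invalid",
                      token, seg, fields[i]), "gaitdyn_parse_error")
    }
    vals[i] <- as.integer(sub(prefixes[i], "", seg))
  }
  trial_key(vals[1], vals[2], vals[3], vals[4], vals[5])
}

#' All 18 standard-protocol trial keys for one subject
#' @param subject Subject number.
#' @param group Group number.
#' @param days Days to include (default both).
#' @return List of [trial_key()] in D/B/T order.
#' @export
subject_trial_keys <- function(subject, group = 1L, days = 1:2) {
  keys <- list()
  for (d in days) for (b in 1:3) for (t in 1:3) {
    keys[[length(keys) + 1L]] <- trial_key(subject, group, d, b, t)
  }
  keys
}
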