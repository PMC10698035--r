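#' Channel role mapping
#'
#' A named character vector mapping the semantic channel roles the analyses
#' need (segment pitch angles, foot and pelvis positions, foot gyroscope
#' pitch rate) to column names of a raw trial. Real exports with vendor
#' headers are ingested by supplying the corresponding map; synthetic trials
#' use [default_channel_map()].
#'
#' @param ... Named role = column-name pairs overriding the defaults.
#' @return Named character vector of class `channel_map`.
#' @export
channel_map <- function(...) {
  m <- default_channel_map()
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(m))
    if (length(bad)) {
      gd_stop(paste0("unknown channel roles: ", paste(bad, collapse = ", ")),
              "gaitdyn_schema_error")
    }
    m[names(over)] <- over
  }
  structure(m, class = "channel_map")
}

#' @rdname channel_map
#' @export
default_channel_map <- function() {
  roles <- c(
    left_thigh_pitch = "left_thigh_pitch_deg",
    right_thigh_pitch = "right_thigh_pitch_deg",
    left_shank_pitch = "left_shank_pitch_deg",
    right_shank_pitch = "right_shank_pitch_deg",
    left_foot_pitch = "left_foot_pitch_deg",
    right_foot_pitch = "right_foot_pitch_deg",
    left_foot_gyro_pitch = "left_foot_gyro_pitch_dps",
    right_foot_gyro_pitch = "right_foot_gyro_pitch_dps",
    left_foot_pos_x = "left_foot_pos_x_m",
    left_foot_pos_y = "left_foot_pos_y_m",
    left_foot_pos_z = "left_foot_pos_z_m",
    right_foot_pos_x = "right_foot_pos_x_m",
    right_foot_pos_y = "right_foot_pos_y_m",
    right_foot_pos_z = "right_foot_pos_z_m",
    pelvis_pos_x = "pelvis_pos_x_m",
    pelvis_pos_y = "pelvis_pos_y_m",
    pelvis_pos_z = "pelvis_pos_z_m"
  )
  structure(roles, class = "channel_map")
}

# Resolve required roles to column indices, with a helpful error.
resolve_roles <- function(trial, map, roles) {
  cols <- unname(unlist(map[roles]))
  missing <- roles[!(cols %in% trial$channel_names)]
  if (length(missing)) {
    gd_stop(paste0("channels missing for roles: ",
                   paste(missing, collapse = ", ")), "gaitdyn_schema_error")
  }
  match(cols, trial$channel_names)
}

#' Extract one mapped channel from a raw trial
#' @param trial A [raw_trial()].
#' @param map A [channel_map()].
#' @param role Role name, e.g. `"right_thigh_pitch"`.
#' @return Numeric vector.
#' @export
trial_channel <- function(trial, role, map = default_channel_map()) {
  trial$channels[, resolve_roles(trial, map, role)]
}

#' Raw kinematic trial
#'
#' One trial's time-stamped multichannel kinematic matrix. A
#' standard-protocol trial holds 4 minutes sampled at 200 Hz: 48,000 rows,
#' a leading `Time` column in milliseconds plus 320 kinematic channels
#' (321 columns in file form). Timestamps must be strictly increasing with
#' uniform spacing and no values may be missing.
#'
#' @param time_ms Numeric vector of timestamps (milliseconds).
#' @param channels Numeric matrix, rows matching `time_ms`, with column names.
#' @param key Optional [trial_key()].
#' @return Object of class `raw_trial` with fields `time_ms`, `channels`,
#'   `channel_names`, `key`.
#' @export
raw_trial <- function(time_ms, channels, key = NULL) {
  channels <- as.matrix(channels)
  if (length(time_ms) < 2) {
    gd_stop("a raw trial needs at least 2 samples", "gaitdyn_invariant_error")
  }
  if (nrow(channels) != length(time_ms)) {
    gd_stop("channel rows must match timestamps", "gaitdyn_invariant_error")
  }
  if (is.null(colnames(channels))) {
    gd_stop("channels must be named", "gaitdyn_invariant_error")
  }
  if (anyNA(time_ms) || anyNA(channels)) {
    gd_stop("raw trial contains missing values", "gaitdyn_invariant_error")
  }
  dt <- diff(time_ms)
  if (any(dt <= 0)) {
    gd_stop("timestamps must be strictly increasing", "gaitdyn_invariant_error")
  }
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-9) {
    gd_stop("timestamps are not uniformly spaced", "gaitdyn_invariant_error")
  }
  structure(list(time_ms = as.numeric(time_ms), channels = channels,
                 channel_names = colnames(channels), key = key),
            class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("<raw_trial> %s: %d samples x %d channels @ %.6g Hz\n",
              if (is.null(x$key)) "(unkeyed)" else format(x$key),
              nrow(x$channels), ncol(x$channels), sampling_rate(x)))
  invisible(x)
}

#' Sampling rate inferred from trial timestamps
#' @param trial A [raw_trial()].
#' @return Sampling frequency in Hz.
#' @export
sampling_rate <- function(trial) {
  1000 / stats::median(diff(trial$time_ms))
}

#' Does a trial have the standard export shape?
#'
#' Standard trials have 48,000 rows and 321 columns in file form
#' (time + 320 channels) at 200 Hz.
#' @param trial A [raw_trial()].
#' @return Logical.
#' @export
is_standard_trial <- function(trial) {
  nrow(trial$channels) == 48000L && ncol(trial$channels) == 320L &&
    abs(sampling_rate(trial) - 200) < 1e-6
}

#' Read a raw trial from a delimited file
#'
#' The file must have a header row whose first column (`Time`) holds
#' timestamps in milliseconds; all remaining columns are kinematic channels.
#'
#' @param path File path.
#' @param map A [channel_map()]; roles required later must resolve to
#'   existing columns (checked lazily by the analyses).
#' @param key Optional [trial_key()]; if `NULL`, parsed from the file name
#'   when it matches the canonical token.
#' @return A [raw_trial()].
#' @export
read_raw_trial <- function(path, map = default_channel_map(), key = NULL) {
  if (!file.exists(path)) gd_stop(paste0("no such file: ", path), "gaitdyn_io_error")
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) gd_stop("trial file has no channel columns", "gaitdyn_schema_error")
  if (is.null(key)) {
    tok <- sub("\\.csv$", "", basename(path))
    key <- tryCatch(parse_trial_id(tok), error = function(e) NULL)
  }
  ch <- as.matrix(dt[, -1, drop = FALSE])
  raw_trial(dt[[1]], ch, key = key)
}

#' Write a raw trial as a delimited file
#'
#' Writes a comma-delimited file with a header row; the first column is
#' named `Time` (milliseconds). Numeric values are fixed at 6 significant
#' digits so that files are bit-stable across runs.
#'
#' @param trial A [raw_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_trial <- function(trial, path) {
  if (!inherits(trial, "raw_trial")) {
    gd_stop("not a raw_trial", "gaitdyn_invariant_error")
  }
  if (nrow(trial$channels) == 0) {
    gd_stop("refusing to write an empty trial", "gaitdyn_invariant_error")
  }
  df <- data.frame(Time = signif(trial$time_ms, 9),
                   signif(trial$channels, 6), check.names = FALSE)
  colnames(df) <- c("Time", trial$channel_names)
  data.table::fwrite(df, path)
  invisible(path)
}
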