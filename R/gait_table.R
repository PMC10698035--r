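#' The 26 spatiotemporal gait parameter columns, in canonical order
#'
#' Column order and units follow the standard per-trial spatiotemporal
#' export: cadence, step time, left/right step length, left/right step
#' width, left/right stride length, left/right stride time, left/right
#' stance time, left/right swing time, single and double support time,
#' left/right percent stance and swing, percent single and double support,
#' average speed, left/right stride speed, and distance traveled.
#'
#' @return Character vector of length 26.
#' @export
gait_parameter_columns <- function() {
  c("cadence (steps/min)", "step time (s)",
    "left step length (cm)", "right step length (cm)",
    "left step width (cm)", "right step width (cm)",
    "left stride length (cm)", "right stride length (cm)",
    "left stride time (s)", "right stride time (s)",
    "left stance time (s)", "right stance time (s)",
    "left swing time (s)", "right swing time (s)",
    "single support time (s)", "double support time (s)",
    "left pct stance (%GC)", "right pct stance (%GC)",
    "left pct swing (%GC)", "right pct swing (%GC)",
    "pct single (%GC)", "pct double (%GC)",
    "average speed (m/s)",
    "left stride speed (m/s)", "right stride speed (m/s)",
    "distance traveled (m)")
}

#' Construct a gait parameter table
#'
#' Series have ragged natural lengths (left and right counts may differ by
#' one; whole-trial scalars such as average speed have length 1); rows are
#' aligned by sample index and shorter series are padded with `NA`.
#'
#' @param series Named list of 26 numeric vectors; names and order must
#'   match [gait_parameter_columns()].
#' @param key Optional [trial_key()].
#' @return A `data.frame` of class `gait_table` with attribute `key`.
#' @export
gait_parameter_table <- function(series, key = NULL) {
  cols <- gait_parameter_columns()
  if (!identical(names(series), cols)) {
    gd_stop("gait table series must match the 26 canonical columns in order",
            "gaitdyn_schema_error")
  }
  validate_gait_series(series)
  n <- max(vapply(series, length, 1L))
  padded <- lapply(series, function(v) c(v, rep(NA_real_, n - length(v))))
  df <- as.data.frame(padded, check.names = FALSE, optional = TRUE)
  colnames(df) <- cols
  structure(df, key = key, class = c("gait_table", "data.frame"))
}

validate_gait_series <- function(series) {
  timecols <- grep("\\(s\\)$", names(series), value = TRUE)
  lencols <- grep("\\(cm\\)$", names(series), value = TRUE)
  for (cn in c(timecols, lencols)) {
    v <- series[[cn]]
    if (length(v) && any(v[!is.na(v)] <= 0)) {
      gd_stop(paste0("non-positive values in '", cn, "'"),
              "gaitdyn_invariant_error")
    }
  }
  for (side in c("left", "right")) {
    st <- series[[paste0(side, " pct stance (%GC)")]]
    sw <- series[[paste0(side, " pct swing (%GC)")]]
    n <- min(length(st), length(sw))
    if (n > 0) {
      s <- st[seq_len(n)] + sw[seq_len(n)]
      if (any(abs(s[!is.na(s)] - 100) > 1e-9)) {
        gd_stop(paste0(side, " pct stance + pct swing must equal 100"),
                "gaitdyn_invariant_error")
      }
    }
  }
  invisible(series)
}

#' Write / read the 26-column spatiotemporal table
#'
#' Files are comma-delimited with the canonical header; missing values in
#' ragged columns are written as empty fields. Values are fixed at 6
#' significant digits for bit-stable files.
#'
#' @param table A [gait_parameter_table()].
#' @param path File path.
#' @return `path` (write) or a `gait_table` (read).
#' @export
write_gait_table <- function(table, path) {
  if (!inherits(table, "gait_table")) {
    gd_stop("not a gait_table", "gaitdyn_schema_error")
  }
  out <- as.data.frame(lapply(table, signif, digits = 6),
                       check.names = FALSE, optional = TRUE)
  colnames(out) <- colnames(table)
  data.table::fwrite(out, path, na = "")
  invisible(path)
}

#' @rdname write_gait_table
#' @export
read_gait_table <- function(path) {
  if (!file.exists(path)) gd_stop(paste0("no such file: ", path), "gaitdyn_io_error")
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  cols <- gait_parameter_columns()
  if (!identical(colnames(df), cols)) {
    gd_stop(sprintf(
      "spatiotemporal table schema mismatch: expected the 26 canonical columns, got %d (%s...)",
      ncol(df), paste(utils::head(colnames(df), 3), collapse = ", ")),
      "gaitdyn_schema_error")
  }
  series <- lapply(df, function(v) {
    v <- as.numeric(v)
    keep <- rev(cumsum(rev(!is.na(v))) > 0)  # strip trailing padding only
    v[keep]
  })
  names(series) <- cols
  key <- tryCatch(parse_trial_id(sub("\\.csv$", "", basename(path))),
                  error = function(e) NULL)
  gait_parameter_table(series, key = key)
}
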