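#' Uniformly sampled signal trace
#'
#' Container for a single-channel time series (photometry, EEG or EMG).
#'
#' @param samples numeric vector, finite values.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample, seconds.
#' @param units free-text unit label.
#' @return object of class `nl_trace`.
#' @export
nl_trace <- function(samples, fs, t0 = 0, units = "a.u.") {
  nl_assert(fs > 0, "fs must be > 0")
  nl_assert(length(samples) > 0, "samples must be nonempty")
  nl_assert(all(is.finite(samples)), "samples must be finite")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0,
                 units = units),
            class = "nl_trace")
}

#' @export
print.nl_trace <- function(x, ...) {
  cat(sprintf("<nl_trace> %d samples @ %g Hz (%.1f s) [%s]\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$units))
  invisible(x)
}

trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$fs
}

trace_duration <- function(trace) length(trace$samples) / trace$fs

#' Write / read a trace as single-column CSV with a JSON sidecar
#'
#' The sidecar `<path>.json` records `fs`, `units` and `t0` so a trace file is
#' self-describing.
#'
#' @param trace an [nl_trace()].
#' @param path CSV file path (sidecar written next to it).
#' @return `read_trace` returns an [nl_trace()].
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(value = trace$samples), path,
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = trace$fs, units = trace$units, t0 = trace$t0),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- utils::read.csv(path)$value
  nl_trace(vals, fs = meta$fs, t0 = meta$t0, units = meta$units)
}

#' Write / read a tracking table as CSV
#'
#' Columns: frame, time_s, nose_x, nose_y, center_x, center_y, tail_x,
#' tail_y, area.  `read_tracking` rebuilds a trajectory (see
#' [trajectory()]); a named `column_map` supports external tables whose
#' columns are named differently.
#'
#' @param traj a [trajectory()].
#' @param path CSV file path.
#' @param column_map optional named character vector mapping the canonical
#'   names to the file's column names.
#' @return `read_tracking` returns a [trajectory()].
#' @export
write_tracking <- function(traj, path) {
  df <- as.data.frame(traj)
  df <- cbind(frame = seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracking
#' @export
read_tracking <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      nl_assert(column_map[[nm]] %in% names(df),
                sprintf("mapped column '%s' not found", column_map[[nm]]),
                "invalid_input")
      names(df)[names(df) == column_map[[nm]]] <- nm
    }
  }
  need <- c("time_s", "nose_x", "nose_y", "center_x", "center_y",
            "tail_x", "tail_y", "area")
  nl_assert(all(need %in% names(df)),
            paste("tracking table missing columns:",
                  paste(setdiff(need, names(df)), collapse = ", ")),
            "invalid_input")
  fs <- if (nrow(df) > 1) 1 / (df$time_s[2] - df$time_s[1]) else 10
  trajectory(time = df$time_s,
             nose = cbind(df$nose_x, df$nose_y),
             center = cbind(df$center_x, df$center_y),
             tail = cbind(df$tail_x, df$tail_y),
             area = df$area, fs = round(fs, 6))
}
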