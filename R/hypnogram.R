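#' Hypnogram: per-epoch vigilance-state labels
#'
#' The temporal backbone shared by every analysis stage: an ordered sequence
#' of Wake/NREM/REM labels on a fixed epoch grid.
#'
#' @param labels character vector of states; `"Wake"/"NREM"/"REM"` or the
#'   short codes `"W"/"N"/"R"`.
#' @param epoch_len epoch length in seconds (> 0).
#' @param start_time time of the first epoch's start, seconds.
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_len = 5, start_time = 0) {
  nl_assert(length(labels) > 0, "labels must be nonempty")
  nl_assert(epoch_len > 0, "epoch_len must be > 0")
  labels <- as.character(labels)
  short <- c(W = "Wake", N = "NREM", R = "REM")
  idx <- labels %in% names(short)
  labels[idx] <- short[labels[idx]]
  nl_assert(all(labels %in% c("Wake", "NREM", "REM")),
            "labels must be Wake/NREM/REM (or W/N/R)")
  structure(list(labels = labels, epoch_len = epoch_len,
                 start_time = start_time),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  occ <- state_occupancy(x)
  cat(sprintf(
    "<hypnogram> %d epochs x %.0f s (%.1f min) | Wake %.0f%% NREM %.0f%% REM %.0f%%\n",
    length(x$labels), x$epoch_len, length(x$labels) * x$epoch_len / 60,
    100 * occ["Wake"], 100 * occ["NREM"], 100 * occ["REM"]))
  invisible(x)
}

hypnogram_duration <- function(hyp) length(hyp$labels) * hyp$epoch_len

# state label at arbitrary times (seconds); times beyond the record -> NA
state_at <- function(hyp, times) {
  idx <- floor((times - hyp$start_time) / hyp$epoch_len) + 1
  out <- rep(NA_character_, length(times))
  ok <- idx >= 1 & idx <= length(hyp$labels)
  out[ok] <- hyp$labels[idx[ok]]
  out
}

#' Extract maximal same-state bouts from a hypnogram
#'
#' @param hyp a [hypnogram()].
#' @return data.frame with columns `state`, `start` (s), `duration` (s);
#'   bout durations sum exactly to the hypnogram duration and the number of
#'   state transitions is `nrow - 1`.
#' @export
extract_bouts <- function(hyp) {
  nl_assert(inherits(hyp, "hypnogram"), "hyp must be a hypnogram")
  r <- rle(hyp$labels)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)]) * hyp$epoch_len + hyp$start_time
  data.frame(state = r$values, start = starts,
             duration = r$lengths * hyp$epoch_len,
             stringsAsFactors = FALSE)
}

#' Fraction of time spent in each vigilance state
#'
#' @param hyp a [hypnogram()].
#' @return named numeric `c(Wake, NREM, REM)` summing to 1; absent states
#'   report 0.
#' @export
state_occupancy <- function(hyp) {
  nl_assert(inherits(hyp, "hypnogram"), "hyp must be a hypnogram")
  states <- c("Wake", "NREM", "REM")
  counts <- vapply(states, function(s) sum(hyp$labels == s), numeric(1))
  counts / length(hyp$labels)
}

#' Write / read a hypnogram as CSV
#'
#' Columns `epoch_start_s` and `state` with single-letter codes W/N/R.
#' @param hyp a [hypnogram()].
#' @param path file path.
#' @return `read_hypnogram` returns a [hypnogram()]; `write_hypnogram`
#'   returns `path` invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  code <- c(Wake = "W", NREM = "N", REM = "R")
  df <- data.frame(
    epoch_start_s = hyp$start_time +
      (seq_along(hyp$labels) - 1) * hyp$epoch_len,
    state = unname(code[hyp$labels]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  epoch_len <- if (nrow(df) > 1) df$epoch_start_s[2] - df$epoch_start_s[1] else 5
  hypnogram(df$state, epoch_len = epoch_len, start_time = df$epoch_start_s[1])
}
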