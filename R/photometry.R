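# Fluorescence normalization, detrending, transient detection and per-state
# activity summaries.

#' Compute delta-F-over-F from a raw fluorescence trace
#'
#' Applies `(F_r - F_m) / F_m`, where `F_r` is the raw signal and `F_m` is
#' the median of either the whole recording (`"recording"`, used for maze and
#' sleep sessions) or the `pre_window` seconds before `event_time`
#' (`"pre_stimulus"`, used for stimulus-aligned recordings).
#'
#' @param raw an [nl_trace()] of raw fluorescence.
#' @param baseline_mode `"recording"` or `"pre_stimulus"`.
#' @param event_time stimulus time (s), required for pre-stimulus mode.
#' @param pre_window seconds before `event_time` used for the baseline
#'   median (default 10).
#' @return an [nl_trace()] of class `c("dff_trace", "nl_trace")` in ΔF/F
#'   units with attributes `f_m` and `baseline_mode`.
#' @export
compute_dff <- function(raw, baseline_mode = c("recording", "pre_stimulus"),
                        event_time = NULL, pre_window = 10) {
  baseline_mode <- match.arg(baseline_mode)
  nl_assert(length(raw$samples) > 0, "raw trace is empty")
  if (baseline_mode == "recording") {
    f_m <- stats::median(raw$samples)
  } else {
    nl_assert(!is.null(event_time) && !is.null(pre_window),
              "pre_stimulus mode requires event_time and pre_window")
    tt <- trace_times(raw)
    sel <- tt >= event_time - pre_window & tt < event_time
    nl_assert(any(sel), "no samples in the pre-stimulus window")
    f_m <- stats::median(raw$samples[sel])
  }
  if (f_m == 0) nl_stop("baseline median is zero; ΔF/F undefined",
                        "degenerate_baseline")
  out <- nl_trace((raw$samples - f_m) / f_m, fs = raw$fs, t0 = raw$t0,
                  units = "dF/F")
  attr(out, "f_m") <- f_m
  attr(out, "baseline_mode") <- baseline_mode
  class(out) <- c("dff_trace", class(out))
  out
}

#' Remove slow baseline drift from a long recording
#'
#' Fits a least-squares polynomial of the given degree to the raw trace and
#' subtracts it, then adds back the pre-fit trace median so the subsequent
#' ΔF/F normalization stays well-scaled.  Traces of 10 minutes or less pass
#' through unchanged (bleaching is negligible at that scale).
#'
#' @param raw an [nl_trace()].
#' @param degree polynomial degree (>= 1), default 2.
#' @return detrended [nl_trace()].
#' @export
detrend_baseline <- function(raw, degree = 2) {
  nl_assert(degree >= 1, "degree must be >= 1")
  if (trace_duration(raw) <= 600) return(raw)
  t <- trace_times(raw)
  ts <- (t - mean(t)) / stats::sd(t)  # scaled for numerical stability
  X <- cbind(1, stats::poly(ts, degree, raw = FALSE, simple = TRUE))
  fit <- stats::lm.fit(X, raw$samples)
  detr <- raw$samples - fit$fitted.values + stats::median(raw$samples)
  nl_trace(detr, fs = raw$fs, t0 = raw$t0, units = raw$units)
}

#' Low-pass a trace with a boxcar filter
#'
#' Light smoothing applied to ΔF/F before transient detection: calcium
#' indicator kinetics are far slower than the sampling rate, so a sub-second
#' boxcar suppresses sample-level noise (which otherwise truncates
#' half-width measurements) without distorting transient amplitude or width.
#'
#' @param trace an [nl_trace()].
#' @param window_s boxcar width, seconds (default 0.25).
#' @return smoothed trace of the same class.
#' @export
smooth_trace <- function(trace, window_s = 0.25) {
  w <- max(1L, round(window_s * trace$fs))
  out <- trace
  out$samples <- boxcar(trace$samples, w)
  out
}

#' Locate the quietest NREM window of a ΔF/F trace
#'
#' Finds the window of the requested length, fully contained in NREM, that
#' minimizes the signal SD — an automatic stand-in for the manually
#' identified "quiet period" used to calibrate transient detection.
#'
#' @param dff a `dff_trace` (or any [nl_trace()]).
#' @param hyp a [hypnogram()] on the same time base.
#' @param length window length, seconds (default 250).
#' @return list `start`, `end` (s), `sd` (the window SD, used as the
#'   detection calibration).
#' @export
find_quiet_period <- function(dff, hyp, length = 250) {
  w <- round(length * dff$fs)
  n <- base::length(dff$samples)
  nl_assert(w >= 2 && w <= n, "window longer than trace")
  st <- state_at(hyp, trace_times(dff))
  is_n <- as.numeric(!is.na(st) & st == "NREM")
  if (sum(is_n) < w) nl_stop("insufficient NREM for the quiet period",
                             "insufficient_data")
  cs <- cumsum(is_n)
  x <- dff$samples
  c1 <- cumsum(x); c2 <- cumsum(x^2)
  starts <- seq_len(n - w + 1)
  in_nrem <- (cs[starts + w - 1] - c(0, cs)[starts]) == w
  if (!any(in_nrem)) nl_stop("no fully-NREM window of the requested length",
                             "insufficient_data")
  s1 <- c1[starts + w - 1] - c(0, c1)[starts]
  s2 <- c2[starts + w - 1] - c(0, c2)[starts]
  v <- (s2 - s1^2 / w) / (w - 1)
  v[!in_nrem] <- Inf
  b <- which.min(v)
  t <- trace_times(dff)
  list(start = t[b], end = t[b + w - 1], sd = sqrt(max(v[b], 0)))
}

# Topographic prominence of local maxima in a 1-D signal.  For each strict
# local maximum: walk left and right to the nearest strictly higher sample
# (or trace edge), track the minimum on each side; prominence = height minus
# the higher of the two minima; bases are the positions of those minima.
peak_prominences <- function(x, peaks) {
  n <- length(x)
  prom <- numeric(length(peaks))
  lb <- integer(length(peaks)); rb <- integer(length(peaks))
  for (j in seq_along(peaks)) {
    p <- peaks[j]; h <- x[p]
    i <- p - 1L; lmin <- h; lpos <- p
    while (i >= 1L && x[i] <= h) {
      if (x[i] < lmin) { lmin <- x[i]; lpos <- i }
      i <- i - 1L
    }
    i <- p + 1L; rmin <- h; rpos <- p
    while (i <= n && x[i] <= h) {
      if (x[i] < rmin) { rmin <- x[i]; rpos <- i }
      i <- i + 1L
    }
    prom[j] <- h - max(lmin, rmin)
    lb[j] <- lpos; rb[j] <- rpos
  }
  list(prominence = prom, left_base = lb, right_base = rb)
}

# half-width (samples) at half-prominence, by linear interpolation
half_width_at <- function(x, p, prom, lb, rb) {
  level <- x[p] - prom / 2
  i <- p
  while (i > lb && x[i - 1] > level) i <- i - 1L
  left <- if (i == p) p else {
    if (x[i - 1] == x[i]) i else (i - 1) + (level - x[i - 1]) / (x[i] - x[i - 1])
  }
  i <- p
  while (i < rb && x[i + 1] > level) i <- i + 1L
  right <- if (i == p) p else {
    if (x[i + 1] == x[i]) i else i + (x[i] - level) / (x[i] - x[i + 1])
  }
  right - left
}

#' Detect calcium transients by peak prominence
#'
#' Finds strict local maxima whose topographic prominence exceeds
#' `prominence_mult` times the quiet-period SD, measures their width at
#' half-prominence, and discards peaks narrower than `min_halfwidth`
#' (1.5 s, filtering electrical/optical artifacts faster than the indicator
#' kinetics).  Transient extents are the prominence base intervals, clipped
#' to ±10 s around the peak and truncated at the minimum between adjacent
#' retained peaks so extents never overlap.
#'
#' @param dff a `dff_trace` (or [nl_trace()]).
#' @param quiet_sd baseline SD from [find_quiet_period()] (> 0).
#' @param prominence_mult prominence threshold in units of `quiet_sd`
#'   (default 3).
#' @param min_halfwidth minimum half-width in seconds (default 1.5).
#' @param max_extent half-extent clip in seconds (default 10).
#' @return data.frame of class `transient_set`: `peak_time`, `amplitude`
#'   (prominence, ΔF/F above the local base), `half_width` (s), `start`,
#'   `end` (extent, s).
#' @export
detect_transients <- function(dff, quiet_sd, prominence_mult = 3,
                              min_halfwidth = 1.5, max_extent = 10) {
  nl_assert(quiet_sd > 0, "quiet_sd must be > 0")
  x <- dff$samples
  n <- length(x)
  thr <- prominence_mult * quiet_sd
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  empty <- data.frame(peak_time = numeric(0), amplitude = numeric(0),
                      half_width = numeric(0), start = numeric(0),
                      end = numeric(0))
  class(empty) <- c("transient_set", class(empty))
  if (!length(cand)) return(empty)
  pr <- peak_prominences(x, cand)
  keep <- pr$prominence > thr
  cand <- cand[keep]
  if (!length(cand)) return(empty)
  prom <- pr$prominence[keep]; lb <- pr$left_base[keep]; rb <- pr$right_base[keep]
  hw <- vapply(seq_along(cand),
               function(j) half_width_at(x, cand[j], prom[j], lb[j], rb[j]),
               numeric(1)) / dff$fs
  keep <- hw >= min_halfwidth
  cand <- cand[keep]; prom <- prom[keep]; lb <- lb[keep]; rb <- rb[keep]
  hw <- hw[keep]
  if (!length(cand)) return(empty)
  # clip extents to +-max_extent and truncate at inter-peak minima
  clip <- round(max_extent * dff$fs)
  lb <- pmax(lb, cand - clip); rb <- pmin(rb, cand + clip)
  if (length(cand) > 1) {
    for (j in seq_len(length(cand) - 1)) {
      if (rb[j] >= lb[j + 1]) {
        between <- cand[j]:cand[j + 1]
        cut <- between[which.min(x[between])]
        rb[j] <- min(rb[j], cut); lb[j + 1] <- max(lb[j + 1], cut)
      }
    }
  }
  t <- trace_times(dff)
  out <- data.frame(peak_time = t[cand], amplitude = prom, half_width = hw,
                    start = t[lb], end = t[rb])
  class(out) <- c("transient_set", class(out))
  out
}

#' Summarize transient activity by vigilance state
#'
#' Assigns each transient to the vigilance state at its peak and reports, per
#' state: count, rate (events per minute of that state's total time), mean
#' amplitude, and the cumulative integral of transient activity — the sum
#' over that state's transients of the trapezoidal integral of the ΔF/F
#' signal minus the linear baseline chord across the transient extent.
#'
#' @param transients a `transient_set` from [detect_transients()].
#' @param dff the `dff_trace` the transients came from.
#' @param hyp a [hypnogram()] on the same time base.
#' @return data.frame, one row per state: `state`, `n_transients`, `rate`
#'   (events/min), `mean_amplitude`, `cumulative_integral` (ΔF/F·s).
#' @export
state_activity_summary <- function(transients, dff, hyp) {
  nl_assert(inherits(hyp, "hypnogram") && length(hyp$labels) > 0,
            "hypnogram must be nonempty", "invalid_argument")
  occ <- state_occupancy(hyp) * hypnogram_duration(hyp)  # seconds per state
  states <- c("Wake", "NREM", "REM")
  st <- if (nrow(transients)) state_at(hyp, transients$peak_time) else character(0)
  t <- trace_times(dff)
  integral_one <- function(i) {
    sel <- which(t >= transients$start[i] & t <= transients$end[i])
    if (length(sel) < 2) return(0)
    y <- dff$samples[sel]
    base <- seq(y[1], y[length(y)], length.out = length(y))
    d <- y - base
    sum(diff(t[sel]) * (d[-length(d)] + d[-1]) / 2)
  }
  ints <- if (nrow(transients)) vapply(seq_len(nrow(transients)), integral_one,
                                       numeric(1)) else numeric(0)
  out <- do.call(rbind, lapply(states, function(s) {
    sel <- !is.na(st) & st == s
    mins <- occ[[s]] / 60
    data.frame(state = s, n_transients = sum(sel),
               rate = if (mins > 0) sum(sel) / mins else NA_real_,
               mean_amplitude = if (any(sel)) mean(transients$amplitude[sel])
                                else NA_real_,
               cumulative_integral = sum(ints[sel]))
  }))
  rownames(out) <- NULL
  out
}

# within-mouse z-score of a per-day value followed by removal of a linear
# across-day trend (OLS residuals); shared by the measured-data summary and
# the ground-truth generator
standardize_values <- function(mouse, day, value) {
  out <- numeric(length(value))
  for (m in unique(mouse)) {
    sel <- mouse == m
    v <- value[sel]
    if (sum(sel) < 2) { out[sel] <- 0; next }
    s <- stats::sd(v)
    z <- if (s > 0) (v - mean(v)) / s else rep(0, length(v))
    d <- day[sel]
    out[sel] <- stats::residuals(stats::lm(z ~ d))
  }
  out
}

#' Standardize per-day NREM transient amplitudes across animals
#'
#' Within each mouse, z-scores the per-day mean NREM transient amplitude,
#' then removes a least-squares linear trend in day index (returning the
#' residuals).  This makes sleep-activity summaries comparable across
#' animals and across the slow drift of a multi-day recording.
#'
#' @param summaries data.frame with columns `mouse`, `day`, `mean_amplitude`.
#' @return the input with an added `standardized` column (per-mouse mean 0).
#' @export
standardize_across_animals <- function(summaries) {
  need <- c("mouse", "day", "mean_amplitude")
  nl_assert(all(need %in% names(summaries)),
            "summaries needs columns mouse, day, mean_amplitude",
            "invalid_argument")
  days_per <- table(summaries$mouse)
  if (any(days_per < 2)) nl_stop("each mouse needs >= 2 days to standardize",
                                 "insufficient_data")
  summaries$standardized <- standardize_values(summaries$mouse, summaries$day,
                                               summaries$mean_amplitude)
  summaries
}

#' Event-aligned average of a ΔF/F trace
#'
#' Extracts a snippet around every event time and returns the snippet matrix
#' with the pointwise mean and SEM (the usual PSTH-style display for
#' stimulus- or transition-aligned photometry).  Events whose window is not
#' fully inside the trace are dropped; the drop count is reported.
#'
#' @param dff a `dff_trace` (or [nl_trace()]).
#' @param event_times event times, seconds.
#' @param window `c(pre, post)` seconds around each event (pre > 0 means
#'   seconds *before* the event).
#' @return list: `time` (s relative to event), `snippets` (events x samples
#'   matrix), `mean`, `sem`, `n_dropped`.
#' @export
align_to_events <- function(dff, event_times, window = c(1, 2)) {
  fs <- dff$fs
  pre <- round(window[1] * fs); post <- round(window[2] * fs)
  t <- trace_times(dff)
  idx <- round((event_times - dff$t0) * fs) + 1
  ok <- idx - pre >= 1 & idx + post <= length(dff$samples)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) warning(sprintf("%d event(s) dropped: partial window",
                                     n_dropped))
  idx <- idx[ok]
  if (!length(idx)) nl_stop("no events with a full window inside the trace",
                            "insufficient_data")
  snip <- t(vapply(idx, function(i) dff$samples[(i - pre):(i + post)],
                   numeric(pre + post + 1)))
  mu <- colMeans(snip)
  sem <- if (nrow(snip) > 1) apply(snip, 2, stats::sd) / sqrt(nrow(snip))
         else rep(0, ncol(snip))
  list(time = seq(-pre, post) / fs, snippets = snip, mean = mu, sem = sem,
       n_dropped = n_dropped)
}
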