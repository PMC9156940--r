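# Rule-based vigilance-state scoring from EEG/EMG in fixed epochs.

as_samples <- function(x, fs = NULL) {
  if (inherits(x, "nl_trace")) list(samples = x$samples, fs = x$fs)
  else {
    nl_assert(!is.null(fs), "fs required when passing a bare numeric trace")
    list(samples = as.numeric(x), fs = fs)
  }
}

# Hann-windowed (modified) periodogram; returns freq (Hz) and power density
periodogram_hann <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xw <- (x - mean(x)) * w
  X <- stats::fft(xw)
  nk <- floor(n / 2) + 1
  p <- (Mod(X[seq_len(nk)])^2) / (fs * sum(w^2))
  p[2:(nk - 1)] <- 2 * p[2:(nk - 1)]
  list(freq = (seq_len(nk) - 1) * fs / n, power = p)
}

#' Per-epoch spectral band powers and EMG tone
#'
#' Splits the traces into consecutive epochs and computes, per epoch, the
#' Hann-periodogram power in the delta (1-4 Hz) and theta (4-10 Hz) bands,
#' broadband power (0.5-25 Hz) and the EMG root-mean-square.  Epochs that
#' overrun the trace are dropped.
#'
#' @param eeg,emg [nl_trace()]s (or numeric vectors with `fs` supplied) of
#'   equal duration.
#' @param fs sampling rate in Hz when bare vectors are passed; must be >= 20
#'   so the 10 Hz theta band edge is resolvable.
#' @param epoch_len epoch length, seconds.
#' @return data.frame of class `epoch_features` with columns `epoch`,
#'   `delta_power`, `theta_power`, `total_power`, `emg_rms`; `epoch_len` and
#'   `fs` stored as attributes.
#' @export
compute_epoch_features <- function(eeg, emg, fs = NULL, epoch_len = 5) {
  e <- as_samples(eeg, fs); m <- as_samples(emg, fs)
  nl_assert(abs(length(e$samples) / e$fs - length(m$samples) / m$fs) <
              min(1 / e$fs, 1 / m$fs) / 2,
            "EEG and EMG traces must have the same duration")
  nl_assert(e$fs >= 20, "fs must be >= 20 Hz to resolve the theta band")
  n_e <- floor(length(e$samples) / (epoch_len * e$fs))
  nl_assert(n_e >= 1, "traces shorter than one epoch")
  ne_eeg <- round(epoch_len * e$fs); ne_emg <- round(epoch_len * m$fs)
  rows <- lapply(seq_len(n_e), function(i) {
    seg <- e$samples[((i - 1) * ne_eeg + 1):(i * ne_eeg)]
    pg <- periodogram_hann(seg, e$fs)
    f <- pg$freq
    seg_m <- m$samples[((i - 1) * ne_emg + 1):(i * ne_emg)]
    data.frame(
      epoch = i,
      delta_power = sum(pg$power[f >= 1 & f <= 4]),
      theta_power = sum(pg$power[f > 4 & f <= 10]),
      total_power = sum(pg$power[f >= 0.5 & f <= 25]),
      emg_rms = sqrt(mean(seg_m^2)))
  })
  out <- do.call(rbind, rows)
  attr(out, "epoch_len") <- epoch_len
  attr(out, "fs") <- e$fs
  class(out) <- c("epoch_features", class(out))
  out
}

# deterministic 1-D 2-means on log values; returns midpoint of the centers
two_class_split <- function(x) {
  lx <- log(x + 1e-12)
  if (max(lx) - min(lx) < 1e-9) {
    nl_stop("EMG features are constant; cannot auto-calibrate thresholds",
            "calibration_failure")
  }
  c1 <- stats::quantile(lx, 0.25, names = FALSE)
  c2 <- stats::quantile(lx, 0.75, names = FALSE)
  for (i in 1:100) {
    lab <- abs(lx - c1) <= abs(lx - c2)
    n1 <- mean(lx[lab]); n2 <- mean(lx[!lab])
    if (!is.finite(n1) || !is.finite(n2)) break
    if (abs(n1 - c1) + abs(n2 - c2) < 1e-12) { c1 <- n1; c2 <- n2; break }
    c1 <- n1; c2 <- n2
  }
  exp((c1 + c2) / 2)
}

#' Classify epochs into Wake / NREM / REM
#'
#' Deterministic rule-based stand-in for manually verified commercial
#' scoring.  Rule order: Wake when EMG RMS exceeds the (auto-calibrated) EMG
#' threshold; else NREM when delta power dominates
#' (`delta_power/total_power > delta_threshold`); else REM when the
#' theta/delta ratio exceeds `theta_ratio_threshold` and the EMG shows
#' atonia; remaining epochs inherit the previous epoch's label (first epoch
#' defaults to Wake).  Single-epoch islands are then absorbed into the
#' preceding bout.
#'
#' @param features an `epoch_features` table from [compute_epoch_features()].
#' @param thresholds `NULL` for auto-calibration, or a list with any of
#'   `emg`, `delta` (default 0.45), `theta_ratio` (default 1.5), `atonia`.
#'   Auto-calibration: `emg` = midpoint of a 2-class 1-D split of
#'   log EMG RMS; `atonia` = 25th percentile of the NREM-candidate EMG RMS.
#' @return a [hypnogram()]; calibrated thresholds in `attr(, "thresholds")`.
#' @export
classify_epochs <- function(features, thresholds = NULL) {
  nl_assert(inherits(features, "epoch_features") && nrow(features) > 0,
            "features must be a nonempty epoch_features table")
  th <- list(delta = 0.45, theta_ratio = 1.5)
  if (!is.null(thresholds)) th[names(thresholds)] <- thresholds
  if (is.null(th$emg)) th$emg <- two_class_split(features$emg_rms)
  delta_frac <- features$delta_power / pmax(features$total_power, 1e-300)
  wake <- features$emg_rms > th$emg
  nrem <- !wake & delta_frac > th$delta
  if (is.null(th$atonia)) {
    th$atonia <- if (any(nrem)) {
      stats::quantile(features$emg_rms[nrem], 0.25, names = FALSE)
    } else th$emg
  }
  theta_ratio <- features$theta_power / pmax(features$delta_power, 1e-300)
  rem <- !wake & !nrem & theta_ratio > th$theta_ratio &
    features$emg_rms < th$atonia
  lab <- rep(NA_character_, nrow(features))
  lab[wake] <- "Wake"; lab[nrem] <- "NREM"; lab[rem] <- "REM"
  for (i in seq_along(lab)) {
    if (is.na(lab[i])) lab[i] <- if (i == 1) "Wake" else lab[i - 1]
  }
  lab <- smooth_islands(lab)
  hyp <- hypnogram(lab, epoch_len = attr(features, "epoch_len"))
  attr(hyp, "thresholds") <- th
  hyp
}

# absorb single-epoch runs into the preceding bout (first run: following one)
smooth_islands <- function(lab) {
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1 || all(r$lengths > 1)) return(lab)
    i <- which(r$lengths == 1)[1]
    r$values[i] <- if (i == 1) r$values[2] else r$values[i - 1]
    lab <- inverse.rle(r)
  }
}

#' Score a sleep recording end to end
#'
#' Convenience wrapper: [compute_epoch_features()] then [classify_epochs()].
#'
#' @inheritParams compute_epoch_features
#' @inheritParams classify_epochs
#' @return a [hypnogram()].
#' @export
score_sleep <- function(eeg, emg, fs = NULL, epoch_len = 5, thresholds = NULL) {
  classify_epochs(compute_epoch_features(eeg, emg, fs, epoch_len), thresholds)
}

#' State-wise relative power spectrum
#'
#' Mean Hann periodogram over all epochs scored as `state`, normalized so the
#' in-band bins sum to 1 (power expressed relative to the state's total
#' in-band power).
#'
#' @param eeg an [nl_trace()] (or numeric with `fs`).
#' @param hyp a [hypnogram()] aligned to the trace.
#' @param state `"Wake"`, `"NREM"` or `"REM"`; must be present.
#' @param band analysis band in Hz, default `c(0.5, 25)`.
#' @param fs sampling rate when `eeg` is a bare vector.
#' @return data.frame `freq`, `relative_power` (sums to 1); state stored as
#'   an attribute.
#' @export
spectral_profile <- function(eeg, hyp, state, band = c(0.5, 25), fs = NULL) {
  e <- as_samples(eeg, fs)
  idx <- which(hyp$labels == state)
  if (!length(idx)) nl_stop(sprintf("state %s absent from hypnogram", state),
                            "empty_state")
  ne <- round(hyp$epoch_len * e$fs)
  acc <- NULL; freq <- NULL
  for (i in idx) {
    i1 <- (i - 1) * ne + 1
    if (i1 + ne - 1 > length(e$samples)) next
    pg <- periodogram_hann(e$samples[i1:(i1 + ne - 1)], e$fs)
    if (is.null(acc)) { acc <- pg$power; freq <- pg$freq }
    else acc <- acc + pg$power
  }
  keep <- freq >= band[1] & freq <= band[2]
  rel <- acc[keep] / sum(acc[keep])
  out <- data.frame(freq = freq[keep], relative_power = rel)
  attr(out, "state") <- state
  out
}

#' Mean EMG RMS per vigilance state
#'
#' @param features an `epoch_features` table.
#' @param hyp a [hypnogram()] with one label per feature row.
#' @return named numeric, one entry per state *present* in the hypnogram
#'   (absent states are omitted, not reported as 0).
#' @export
emg_rms_by_state <- function(features, hyp) {
  nl_assert(nrow(features) == length(hyp$labels),
            "features and hypnogram lengths differ")
  states <- intersect(c("Wake", "NREM", "REM"), unique(hyp$labels))
  vapply(states, function(s) mean(features$emg_rms[hyp$labels == s]),
         numeric(1))
}
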