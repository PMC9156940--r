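# Synthetic sleep-side generators: hypnograms, EEG/EMG, photometry.

#' Simulate a semi-Markov hypnogram
#'
#' Alternates Wake/NREM/REM bouts with truncated-exponential dwell times and
#' the transition grammar Wake->NREM, NREM->(Wake|REM), REM->(Wake|NREM).
#' REM is forbidden before `config$rem_latency` seconds from recording onset,
#' reproducing the empirical observation that REM episodes are absent early
#' in a rest period.  Bout lengths are quantized to whole epochs so bout
#' durations always sum exactly to the requested duration.
#'
#' @param config a [sim_config()].
#' @param duration recording length, seconds (>= one epoch).
#' @param seed integer seed.
#' @return a [hypnogram()] whose `attr(, "bouts")` holds the generating bout
#'   table.
#' @export
simulate_hypnogram <- function(config, duration = config$rest_duration,
                               seed = config$seed) {
  nl_assert(duration >= config$epoch_len,
            "duration must be at least one epoch")
  epoch <- config$epoch_len
  n_epochs <- floor(duration / epoch)
  with_seed(seed, {
    labels <- character(0)
    state <- "Wake"
    t_now <- 0
    while (length(labels) < n_epochs) {
      p <- config$state_dwell_params[[state]]
      dwell <- min(stats::rexp(1, 1 / p$mean), p$max)
      n_ep <- max(1L, as.integer(round(dwell / epoch)))
      labels <- c(labels, rep(state, n_ep))
      t_now <- length(labels) * epoch
      state <- switch(state,
        Wake = "NREM",
        NREM = if (t_now >= config$rem_latency &&
                     stats::runif(1) < config$p_rem) "REM" else "Wake",
        REM = if (stats::runif(1) < config$p_rem_to_wake) "Wake" else "NREM")
    }
    labels <- labels[seq_len(n_epochs)]
  })
  hyp <- hypnogram(labels, epoch_len = epoch, start_time = 0)
  attr(hyp, "bouts") <- extract_bouts(hyp)
  hyp
}

# unit-variance Gaussian noise band-limited to [lo, hi] Hz via FFT masking
band_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # two-sided spectrum
  mask <- freqs >= lo & freqs <= hi
  mask[1] <- FALSE
  X[!mask] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

#' Synthesize EEG and EMG traces consistent with a hypnogram
#'
#' Each epoch's EEG is a weighted sum of delta-band (1-4 Hz), theta-band
#' (4-10 Hz) and broadband (0.5-25 Hz) unit-variance noise; NREM epochs are
#' delta-dominated and high-amplitude, REM epochs theta-dominated, Wake
#' epochs low-amplitude broadband.  EMG is white noise whose SD is high in
#' Wake, intermediate in NREM and minimal (atonia) in REM.
#'
#' @param hyp a [hypnogram()].
#' @param config a [sim_config()]; `eeg_weights` and `emg_sd` control the
#'   state-dependent composition.
#' @param seed integer seed.
#' @return list with `eeg` and `emg` ([nl_trace()]s at `config$eeg_fs`).
#' @export
synth_eeg_emg <- function(hyp, config, seed = config$seed) {
  nl_assert(inherits(hyp, "hypnogram") && length(hyp$labels) > 0,
            "hyp must be a nonempty hypnogram")
  fs <- config$eeg_fs
  n_per <- round(hyp$epoch_len * fs)
  n_epochs <- length(hyp$labels)
  eeg <- numeric(n_per * n_epochs)
  emg <- numeric(n_per * n_epochs)
  with_seed(seed, {
    for (i in seq_len(n_epochs)) {
      st <- hyp$labels[i]
      w <- config$eeg_weights[[st]]
      seg <- w[["delta"]] * band_noise(n_per, fs, 1, 4) +
        w[["theta"]] * band_noise(n_per, fs, 4, 10) +
        w[["broad"]] * band_noise(n_per, fs, 0.5, 25)
      idx <- ((i - 1) * n_per + 1):(i * n_per)
      eeg[idx] <- seg
      emg[idx] <- stats::rnorm(n_per, sd = config$emg_sd[[st]])
    }
  })
  list(eeg = nl_trace(eeg, fs = fs, units = "uV"),
       emg = nl_trace(emg, fs = fs, units = "uV"))
}

# GCaMP6s-like kernel: peak-normalized double exponential, value A at peak
transient_kernel <- function(t, tau_rise = 0.2, tau_decay = 2) {
  tp <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  peak <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak
}

#' Synthesize a raw photometry trace with state-dependent transients
#'
#' Transient onset times follow a Poisson process whose rate depends on the
#' concurrent vigilance state (events/min, `config$transient_rates`); each
#' event adds a peak-normalized double-exponential kernel (rise 0.2 s, decay
#' 2 s) scaled by a state-dependent Gaussian amplitude.  A polynomial
#' baseline drift (`config$drift_coeffs`, emulating slow photobleaching) and
#' white noise complete the trace.
#'
#' @param hyp a [hypnogram()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list: `trace` (raw-fluorescence [nl_trace()] at `config$photo_fs`)
#'   and `events` (data.frame `time`, `peak_time`, `amplitude`, `state` of
#'   ground-truth transients; `peak_time` is where the kernel peaks).
#' @export
synth_photometry <- function(hyp, config, seed = config$seed) {
  nl_assert(inherits(hyp, "hypnogram") && length(hyp$labels) > 0,
            "hyp must be a nonempty hypnogram")
  nl_assert(all(config$transient_rates >= 0),
            "transient rates must be >= 0")
  fs <- config$photo_fs
  duration <- hypnogram_duration(hyp)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  bouts <- extract_bouts(hyp)
  tau_rise <- 0.2; tau_decay <- 2
  t_peak_offset <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  ev_time <- numeric(0); ev_amp <- numeric(0); ev_state <- character(0)
  trace <- config$baseline_f + polyval(config$drift_coeffs, t)
  with_seed(seed, {
    for (b in seq_len(nrow(bouts))) {
      st <- bouts$state[b]
      rate <- config$transient_rates[[st]] / 60  # events/s
      if (rate <= 0) next
      k <- stats::rpois(1, rate * bouts$duration[b])
      if (k == 0) next
      times <- sort(stats::runif(k, bouts$start[b],
                                 bouts$start[b] + bouts$duration[b]))
      # hard-core refractory thinning: drop onsets closer than min_sep to
      # the previously kept one (population events are discrete; onsets
      # within the indicator kernel width are unresolvable by construction)
      if (length(times) > 1 && config$transient_min_sep > 0) {
        keep <- times[1]
        for (tt in times[-1]) {
          if (tt - keep[length(keep)] >= config$transient_min_sep) {
            keep <- c(keep, tt)
          }
        }
        times <- keep
        k <- length(times)
      }
      ap <- config$transient_amp_params[[st]]
      amps <- pmax(0.5, stats::rnorm(k, ap[["mean"]], ap[["sd"]]))
      ev_time <- c(ev_time, times)
      ev_amp <- c(ev_amp, amps)
      ev_state <- c(ev_state, rep(st, k))
    }
    # kernel support truncated at 12 s (< 0.3% of peak remains)
    kern_n <- round(12 * fs)
    kern_t <- (seq_len(kern_n) - 1) / fs
    kern <- transient_kernel(kern_t, tau_rise, tau_decay)
    for (j in seq_along(ev_time)) {
      i0 <- floor(ev_time[j] * fs) + 1
      i1 <- min(n, i0 + kern_n - 1)
      if (i0 > n) next
      trace[i0:i1] <- trace[i0:i1] + ev_amp[j] * kern[seq_len(i1 - i0 + 1)]
    }
    if (config$noise_sd > 0) {
      trace <- trace + stats::rnorm(n, sd = config$noise_sd)
    }
  })
  events <- data.frame(time = ev_time, peak_time = ev_time + t_peak_offset,
                       amplitude = ev_amp, state = ev_state,
                       stringsAsFactors = FALSE)
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  list(trace = nl_trace(trace, fs = fs, units = "F"), events = events)
}
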