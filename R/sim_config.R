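#' Configuration for the synthetic multimodal experiment generator
#'
#' Collects every tunable of the simulated world: experiment layout
#' (mice x days x trials), sleep-bout dynamics, state-dependent EEG/EMG
#' spectral composition, photometry transient statistics, maze geometry and
#' the coupling coefficient that links standardized NREM transient amplitude
#' on one day to the log-odds of slow, investigative port visits on the next.
#'
#' Defaults describe the emulated experiment: 4 mice recorded over 4
#' consecutive days, 5 maze trials per day followed by a 4 h home-cage rest,
#' vigilance scored in 5 s epochs, photometry sampled at 400 Hz and video
#' tracking at 10 Hz.  Dwell-time means (Wake 4 min, NREM 8 min, REM 1.5 min,
#' REM capped at 2 min) produce hypnograms in which most time is spent in
#' NREM, least in REM, and REM is absent from the first hour of rest.
#'
#' @param seed integer base seed; all randomness in a generated dataset is
#'   derived deterministically from it.
#' @param n_mice,n_days,trials_per_day experiment layout counts.
#' @param rest_duration seconds of home-cage rest recorded per day.
#' @param epoch_len vigilance-scoring epoch length in seconds.
#' @param eeg_fs,photo_fs,track_fs sampling rates (Hz) of EEG/EMG, photometry
#'   and video tracking.
#' @param state_dwell_params named list per state with `mean` and `max` dwell
#'   seconds of the truncated-exponential bout-length distributions.
#' @param rem_latency seconds from rest onset before which REM is forbidden.
#' @param p_rem probability that a NREM bout (after the latency) is followed
#'   by REM rather than Wake.
#' @param p_rem_to_wake probability that a REM bout is followed by Wake
#'   (otherwise NREM).
#' @param transient_rates named events/min per state for photometry events.
#' @param transient_min_sep minimum separation (s) enforced between
#'   successive transient onsets (hard-core refractory thinning of the
#'   Poisson draws); population calcium events are discrete and, given the
#'   ~2 s indicator decay, onsets closer than the kernel width would be
#'   physically unresolvable.
#' @param transient_amp_params named list per state, each `c(mean, sd)` of the
#'   raw-fluorescence transient peak amplitude.
#' @param baseline_f raw fluorescence baseline level (arbitrary units).
#' @param drift_coeffs polynomial coefficients (increasing degree, intercept
#'   first) of the slow baseline drift added to raw fluorescence, evaluated in
#'   seconds.
#' @param noise_sd white-noise SD of the raw fluorescence trace.
#' @param eeg_weights named list per state of `c(delta, theta, broad)`
#'   amplitude weights for the EEG synthesis mixture.
#' @param emg_sd named per-state SD of the synthetic EMG trace.
#' @param arena_diameter maze arena diameter (cm).
#' @param n_ports number of escape ports around the arena edge.
#' @param coupling dimensionless coefficient: slow-visit log-odds per unit of
#'   standardized NREM transient amplitude in the preceding rest.
#' @param slow_speed_mu,fast_speed_mu mean nose speed (cm/s) of the slow
#'   investigative and fast pass-and-go port-visit motifs.
#' @param speed_sd SD (cm/s) of the per-visit speed draw around its motif mean.
#' @param trial_duration nominal maze trial duration cap in seconds.
#' @param visits_per_trial expected number of port visits per trial.
#' @param port_bias geometric concentration of visited ports around the
#'   correct port (0 = uniform, values near 1 concentrate strongly); emulates
#'   spatial memory focusing search near the remembered escape location.
#' @return object of class `sim_config` (a validated named list).
#' @seealso [sim_config_desk()] for a scaled-down configuration used in tests.
#' @export
sim_config <- function(seed = 1L,
                       n_mice = 4L,
                       n_days = 4L,
                       trials_per_day = 5L,
                       rest_duration = 14400,
                       epoch_len = 5,
                       eeg_fs = 100,
                       photo_fs = 400,
                       track_fs = 10,
                       state_dwell_params = list(
                         Wake = list(mean = 240, max = 1200),
                         NREM = list(mean = 480, max = 1800),
                         REM  = list(mean = 90,  max = 120)
                       ),
                       rem_latency = 3600,
                       p_rem = 0.35,
                       p_rem_to_wake = 0.6,
                       transient_rates = c(Wake = 4, NREM = 2, REM = 10),
                       transient_min_sep = 3,
                       transient_amp_params = list(
                         Wake = c(mean = 4, sd = 1),
                         NREM = c(mean = 3, sd = 0.8),
                         REM  = c(mean = 5, sd = 1.2)
                       ),
                       baseline_f = 100,
                       drift_coeffs = c(0, -2e-4),
                       noise_sd = 0.3,
                       eeg_weights = list(
                         Wake = c(delta = 0.8, theta = 0.8, broad = 1.0),
                         NREM = c(delta = 4.0, theta = 1.0, broad = 0.5),
                         REM  = c(delta = 0.6, theta = 3.0, broad = 0.5)
                       ),
                       emg_sd = c(Wake = 1.0, NREM = 0.35, REM = 0.05),
                       arena_diameter = 120,
                       n_ports = 8L,
                       coupling = 1,
                       slow_speed_mu = 5,
                       fast_speed_mu = 25,
                       speed_sd = 2,
                       trial_duration = 90,
                       visits_per_trial = 6,
                       port_bias = 0.5) {
  cfg <- list(
    seed = as.integer(seed), n_mice = as.integer(n_mice),
    n_days = as.integer(n_days), trials_per_day = as.integer(trials_per_day),
    rest_duration = rest_duration, epoch_len = epoch_len,
    eeg_fs = eeg_fs, photo_fs = photo_fs, track_fs = track_fs,
    state_dwell_params = state_dwell_params, rem_latency = rem_latency,
    p_rem = p_rem, p_rem_to_wake = p_rem_to_wake,
    transient_rates = transient_rates,
    transient_min_sep = transient_min_sep,
    transient_amp_params = transient_amp_params,
    baseline_f = baseline_f, drift_coeffs = drift_coeffs, noise_sd = noise_sd,
    eeg_weights = eeg_weights, emg_sd = emg_sd,
    arena_diameter = arena_diameter, n_ports = as.integer(n_ports),
    coupling = coupling, slow_speed_mu = slow_speed_mu,
    fast_speed_mu = fast_speed_mu, speed_sd = speed_sd,
    trial_duration = trial_duration, visits_per_trial = visits_per_trial,
    port_bias = port_bias
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  nl_assert(cfg$n_mice >= 1 && cfg$n_days >= 1 && cfg$trials_per_day >= 1,
            "n_mice, n_days and trials_per_day must be positive")
  nl_assert(cfg$rest_duration > 0 && cfg$epoch_len > 0 &&
              cfg$trial_duration > 0,
            "all durations must be > 0")
  nl_assert(cfg$eeg_fs > 0 && cfg$photo_fs > 0 && cfg$track_fs > 0,
            "sampling rates must be > 0")
  nl_assert(all(cfg$transient_rates >= 0), "transient rates must be >= 0")
  nl_assert(all(c("Wake", "NREM", "REM") %in% names(cfg$state_dwell_params)),
            "state_dwell_params must name Wake, NREM and REM")
  nl_assert(all(vapply(cfg$state_dwell_params,
                       function(p) p$mean > 0 && p$max > 0, logical(1))),
            "dwell-time parameters must be > 0")
  nl_assert(cfg$arena_diameter > 0, "arena_diameter must be > 0")
  nl_assert(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  nl_assert(cfg$rem_latency >= 0, "rem_latency must be >= 0")
  nl_assert(cfg$port_bias >= 0 && cfg$port_bias < 1,
            "port_bias must be in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Scaled-down simulation configuration for desk-scale runs
#'
#' Same world as [sim_config()] but with a shorter rest recording and lower
#' photometry sampling rate so full multi-day datasets generate in seconds.
#' Rates, amplitudes, dwell-time distributions and the behavioral coupling are
#' unchanged, so statistical round trips behave as at full scale; only
#' quantities that accumulate over recording length (e.g. total transient
#' counts) shrink proportionally.
#'
#' @param ... overrides forwarded to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_desk <- function(...) {
  args <- list(...)
  defaults <- list(rest_duration = 1800, photo_fs = 50, eeg_fs = 100,
                   rem_latency = 450)
  for (nm in names(defaults)) {
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  }
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d mice x %d days x %d trials/day; rest %.0f s\n",
              x$n_mice, x$n_days, x$trials_per_day, x$rest_duration))
  cat(sprintf("  epoch %.0f s | eeg %g Hz | photo %g Hz | track %g Hz\n",
              x$epoch_len, x$eeg_fs, x$photo_fs, x$track_fs))
  cat(sprintf("  coupling %.3g; slow/fast visit speeds %.3g / %.3g cm/s\n",
              x$coupling, x$slow_speed_mu, x$fast_speed_mu))
  invisible(x)
}
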