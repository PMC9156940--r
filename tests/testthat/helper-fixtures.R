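# Shared fixtures (memoized: heavy synthetic datasets are built once per
# test run) and independent oracles used across test files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(builder)()
  .fx[[name]]
}

# one desk-scale sleep recording with EEG/EMG and photometry
fx_sleep <- function() fixture("sleep", function() {
  cfg <- sim_config_desk(seed = 2)
  hyp <- simulate_hypnogram(cfg, 1800, seed = 2)
  raw <- synth_eeg_emg(hyp, cfg, seed = 4)
  ph <- synth_photometry(hyp, cfg, seed = 5)
  list(cfg = cfg, hyp = hyp, eeg = raw$eeg, emg = raw$emg,
       photo = ph$trace, events = ph$events)
})

# a bank of maze trials (2 mice x 2 days x 3 trials) for clustering tests
fx_trials <- function() fixture("trials", function() {
  cfg <- sim_config_desk(seed = 1)
  trials <- list()
  for (m in 1:2) for (d in 1:2) for (t in 1:3) {
    tr <- synth_maze_session(0, cfg, seed = m * 100 + d * 10 + t,
                             correct_port = m)
    tr$mouse <- m; tr$day <- d; tr$trial <- t
    trials[[length(trials) + 1]] <- tr
  }
  trials
})

fx_dataset <- function() fixture("dataset", function() {
  build_window_dataset(fx_trials())
})

fx_model <- function() fixture("model", function() {
  train_cluster_model(fx_dataset(), cluster_config(epochs = 10, seed = 2))
})

# coupled multi-day dataset (ground truth only, no raw traces)
fx_multiday <- function() fixture("multiday", function() {
  synth_multiday_experiment(
    sim_config_desk(seed = 11, n_mice = 6, coupling = 1),
    include_raw = FALSE)
})

# ---- independent oracles -------------------------------------------------

# Brute-force transient detection: direct definition of topographic
# prominence and half-prominence width, O(n^2) scans, no shared code with
# detect_transients beyond base R.
oracle_detect <- function(x, fs, quiet_sd, prominence_mult = 3,
                          min_halfwidth = 1.5) {
  n <- length(x)
  res <- NULL
  for (i in seq(2, n - 1)) {
    if (!(x[i] > x[i - 1] && x[i] > x[i + 1])) next
    h <- x[i]
    lmin <- h; j <- i - 1
    lstop <- 0
    while (j >= 1) {
      if (x[j] > h) { lstop <- j; break }
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1
    }
    rmin <- h; j <- i + 1
    while (j <= n) {
      if (x[j] > h) break
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1
    }
    prom <- h - max(lmin, rmin)
    if (prom <= prominence_mult * quiet_sd) next
    level <- h - prom / 2
    j <- i
    while (j > 1 && x[j - 1] > level) j <- j - 1
    left <- if (j == i) i else (j - 1) + (level - x[j - 1]) / (x[j] - x[j - 1])
    j <- i
    while (j < n && x[j + 1] > level) j <- j + 1
    right <- if (j == i) i else j + (x[j] - level) / (x[j] - x[j + 1])
    hw <- (right - left) / fs
    if (hw < min_halfwidth) next
    res <- rbind(res, data.frame(peak = i, prominence = prom, half_width = hw))
  }
  res
}

# construct a trajectory moving through a list of (x, y, speed) waypoints
make_path_traj <- function(waypoints, fs = 10, nose_offset = 2) {
  pts <- matrix(waypoints[[1]][1:2], ncol = 2)
  for (k in seq(2, length(waypoints))) {
    from <- pts[nrow(pts), ]
    to <- waypoints[[k]][1:2]
    v <- waypoints[[k]][3]
    d <- sqrt(sum((to - from)^2))
    n_steps <- max(1, round(d / (v / fs)))
    fr <- seq_len(n_steps) / n_steps
    pts <- rbind(pts, cbind(from[1] + fr * (to[1] - from[1]),
                            from[2] + fr * (to[2] - from[2])))
  }
  n <- nrow(pts)
  dx <- c(diff(pts[, 1]), 0); dy <- c(diff(pts[, 2]), 0)
  nrm <- sqrt(dx^2 + dy^2); z <- nrm < 1e-9
  dx[z] <- 1; dy[z] <- 0; nrm[z] <- 1
  u <- cbind(dx / nrm, dy / nrm)
  trajectory(time = (seq_len(n) - 1) / fs,
             nose = pts + nose_offset * u, center = pts,
             tail = pts - nose_offset * u,
             area = rep(12, n), fs = fs)
}

# stationary trajectory at a point, nose pointing along +x
make_still_traj <- function(x, y, n = 50, fs = 10, nose_offset = 2) {
  pts <- cbind(rep(x, n), rep(y, n))
  trajectory(time = (seq_len(n) - 1) / fs,
             nose = cbind(pts[, 1] + nose_offset, pts[, 2]), center = pts,
             tail = cbind(pts[, 1] - nose_offset, pts[, 2]),
             area = rep(12, n), fs = fs)
}
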