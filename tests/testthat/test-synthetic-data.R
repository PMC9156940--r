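# Generators: hypnograms, EEG/EMG, photometry, maze and object trajectories,
# multi-day assembly.

test_that("simulate_hypnogram conserves duration, respects REM latency and errors", {
  cfg <- sim_config_desk()
  hyp <- simulate_hypnogram(cfg, 3600, seed = 1)
  expect_length(hyp$labels, 720)
  expect_equal(sum(extract_bouts(hyp)$duration), 3600)

  cfg_lat <- sim_config_desk(rem_latency = 3600)
  for (s in 1:20) {
    h <- simulate_hypnogram(cfg_lat, 3600, seed = s)
    expect_false("REM" %in% h$labels)
  }
  expect_error(simulate_hypnogram(cfg, 2, seed = 1),
               class = "nremlink_invalid_argument")
})

test_that("hypnogram state fractions order as configured (Monte-Carlo)", {
  cfg <- sim_config_desk()
  occ <- vapply(1:200, function(s)
    state_occupancy(simulate_hypnogram(cfg, 1800, seed = s)), numeric(3))
  m <- rowMeans(occ)
  expect_gt(m["NREM"], m["Wake"])
  expect_gt(m["Wake"], m["REM"])
  # full-scale config, smaller replicate count for runtime
  cfg4 <- sim_config()
  occ4 <- vapply(1:25, function(s)
    state_occupancy(simulate_hypnogram(cfg4, 14400, seed = s)), numeric(3))
  m4 <- rowMeans(occ4)
  expect_gt(m4["NREM"], m4["Wake"])
  expect_gt(m4["Wake"], m4["REM"])
})

test_that("generators are deterministic given config + seed", {
  cfg <- sim_config_desk(seed = 9)
  h1 <- simulate_hypnogram(cfg, 600, seed = 3)
  h2 <- simulate_hypnogram(cfg, 600, seed = 3)
  expect_identical(h1$labels, h2$labels)
  p1 <- synth_photometry(h1, cfg, seed = 4)
  p2 <- synth_photometry(h2, cfg, seed = 4)
  expect_identical(p1$trace$samples, p2$trace$samples)
  expect_identical(p1$events, p2$events)
  t1 <- synth_maze_session(0.5, cfg, seed = 5)
  t2 <- synth_maze_session(0.5, cfg, seed = 5)
  expect_identical(t1$nose, t2$nose)
  e1 <- synth_eeg_emg(hypnogram(rep("NREM", 6)), cfg, seed = 6)
  e2 <- synth_eeg_emg(hypnogram(rep("NREM", 6)), cfg, seed = 6)
  expect_identical(e1$eeg$samples, e2$eeg$samples)
})

test_that("synth_eeg_emg band structure and EMG tone follow the state", {
  cfg <- sim_config_desk()
  all_n <- synth_eeg_emg(hypnogram(rep("NREM", 24)), cfg, seed = 1)
  f_n <- compute_epoch_features(all_n$eeg, all_n$emg, epoch_len = 5)
  expect_true(all(f_n$delta_power > f_n$theta_power))

  all_r <- synth_eeg_emg(hypnogram(rep("REM", 24)), cfg, seed = 2)
  all_w <- synth_eeg_emg(hypnogram(rep("Wake", 24)), cfg, seed = 3)
  rms <- function(x) sqrt(mean(x$samples^2))
  expect_lt(rms(all_r$emg), rms(all_w$emg))
  # sample counts = duration x fs
  expect_length(all_n$eeg$samples, 24 * 5 * cfg$eeg_fs)
})

test_that("synth_photometry: zero rates give the exact drift polynomial", {
  cfg <- sim_config_desk(transient_rates = c(Wake = 0, NREM = 0, REM = 0),
                         noise_sd = 0, drift_coeffs = c(1, -2e-4, 1e-7))
  hyp <- hypnogram(rep(c("Wake", "NREM"), 30))
  out <- synth_photometry(hyp, cfg, seed = 1)
  t <- (seq_along(out$trace$samples) - 1) / cfg$photo_fs
  expected <- cfg$baseline_f + 1 - 2e-4 * t + 1e-7 * t^2
  expect_equal(out$trace$samples, expected, tolerance = 1e-12)
  expect_equal(nrow(out$events), 0)
  expect_error(
    synth_photometry(hyp, sim_config_desk(transient_rates = c(Wake = -1, NREM = 0, REM = 0))),
    class = "nremlink_invalid_argument")
})

test_that("photometry event counts follow per-state rates and durations", {
  # REM 10/min vs NREM 2/min, 30 min each: REM count larger in >= 95% seeds
  cfg <- sim_config_desk(transient_rates = c(Wake = 0, NREM = 2, REM = 10),
                         transient_min_sep = 0)
  hyp <- hypnogram(rep(c("NREM", "REM"), each = 360))  # 30 min each
  wins <- vapply(1:100, function(s) {
    ev <- synth_photometry(hyp, cfg, seed = s)$events
    sum(ev$state == "REM") > sum(ev$state == "NREM")
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  # equal rates/amplitudes, 180 min NREM vs 20 min REM: cumulative true
  # amplitude mass ~9x larger in NREM (expectation ratio, Monte-Carlo)
  cfg2 <- sim_config_desk(transient_rates = c(Wake = 0, NREM = 3, REM = 3),
                          transient_amp_params = list(
                            Wake = c(mean = 3, sd = 0.5),
                            NREM = c(mean = 3, sd = 0.5),
                            REM = c(mean = 3, sd = 0.5)),
                          photo_fs = 20)
  hyp2 <- hypnogram(c(rep("NREM", 2160), rep("REM", 240)))
  ev <- synth_photometry(hyp2, cfg2, seed = 7)$events
  mass <- tapply(ev$amplitude, ev$state, sum)
  expect_gt(mass[["NREM"]], mass[["REM"]])
  expect_equal(unname(mass[["NREM"]] / mass[["REM"]]), 9, tolerance = 0.35)
})

test_that("maze sessions stay in the arena and honor the drive", {
  cfg <- sim_config_desk()
  tr <- synth_maze_session(0, cfg, seed = 3)
  expect_true(all(sqrt(rowSums(tr$center^2)) <= 60))
  expect_error(synth_maze_session(0, cfg, trial_duration = 5, seed = 1),
               class = "nremlink_invalid_argument")

  # drive = +4: logistic(4) ~ 0.982, so >= 90% slow across 50 seeds
  lab <- unlist(lapply(1:50, function(s)
    attr(synth_maze_session(4, cfg, seed = s), "visits")$motif))
  expect_gte(mean(lab == "slow"), 0.9)

  # drive = 0: slow fraction in a binomial band around 0.5
  lab0 <- character(0); s <- 0
  while (length(lab0) < 200) {
    s <- s + 1
    lab0 <- c(lab0, attr(synth_maze_session(0, cfg, seed = 1000 + s),
                         "visits")$motif)
  }
  expect_gt(mean(lab0 == "slow"), 0.35)
  expect_lt(mean(lab0 == "slow"), 0.65)
})

test_that("trajectory sample counts and visit ground truth are consistent", {
  cfg <- sim_config_desk()
  tr <- synth_maze_session(1, cfg, seed = 8)
  expect_equal(length(tr$time), nrow(tr$nose))
  expect_true(all(diff(tr$time) > 0))
  gt <- attr(tr, "visits")
  if (!is.null(gt) && nrow(gt)) {
    expect_true(all(gt$motif %in% c("slow", "fast")))
    expect_true(all(gt$entry_time >= 0 &
                      gt$entry_time <= max(tr$time)))
  }
})

test_that("object sessions plant the novelty preference", {
  cfg <- sim_config_desk()
  expect_equal(novelty_preference(synth_object_session(1, cfg, 300, seed = 2)), 1)
  expect_equal(novelty_preference(synth_object_session(0, cfg, 300, seed = 3)), 0)
  rs <- vapply(1:50, function(s)
    novelty_preference(synth_object_session(0.5, cfg, 600, seed = s)),
    numeric(1))
  expect_gt(mean(rs), 0.4)
  expect_lt(mean(rs), 0.6)
  expect_error(synth_object_session(1.2, cfg, 60, seed = 1),
               class = "nremlink_invalid_argument")
})

test_that("multi-day experiment has the right shape and planted coupling sign", {
  ds <- fx_multiday()   # 6 mice x 4 days x 5 trials, coupling 1
  expect_length(ds$rests, 24)
  expect_length(ds$trials, 120)
  gt <- ds$ground_truth
  expect_equal(gt$coupling, 1)
  # day-1 drives are zero; later drives equal coupling x previous-day activity
  expect_true(all(gt$drive$drive[gt$drive$day == 1] == 0))
  for (i in which(gt$drive$day > 1)) {
    prev <- gt$nrem_activity$standardized[
      gt$nrem_activity$mouse == gt$drive$mouse[i] &
        gt$nrem_activity$day == gt$drive$day[i] - 1]
    expect_equal(gt$drive$drive[i], 1 * prev)
  }
  # positive coupling: next-day mean visit speed anti-correlates with
  # preceding NREM activity (slow motif has low speed)
  ct <- coupling_table(ds, use_true_labels = TRUE)
  vis <- gt$visits
  spd <- stats::aggregate(target_speed ~ mouse + day, vis, mean)
  j <- merge(spd, ct, by = c("mouse", "day"))
  expect_lt(stats::cor(j$target_speed, j$activity), 0)
})

test_that("coupling = 0 leaves speed-activity correlations centered on zero", {
  # ~36 usable mouse-days per replicate: the expected null |r| is
  # ~0.8/sqrt(n), so the 0.15 bound needs this scale to be meaningful
  rs <- vapply(1:20, function(s) {
    cfg <- sim_config_desk(seed = 3000 + s, n_mice = 6, n_days = 7,
                           coupling = 0)
    ds <- synth_multiday_experiment(cfg, include_raw = FALSE)
    vis <- ds$ground_truth$visits
    ct <- coupling_table(ds, use_true_labels = TRUE)
    spd <- stats::aggregate(target_speed ~ mouse + day, vis, mean)
    j <- merge(spd, ct, by = c("mouse", "day"))
    stats::cor(j$target_speed, j$activity)
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.15)
})
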