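# dF/F, detrending, quiet-period calibration, transient detection (vs the
# brute-force oracle), per-state summaries, cross-animal standardization,
# event alignment.

test_that("compute_dff implements (F_r - F_m)/F_m with both baselines", {
  const <- nl_trace(rep(7, 100), fs = 10)
  expect_true(all(compute_dff(const)$samples == 0))

  raw <- nl_trace(c(rep(2, 99), 4), fs = 10)   # median 2, one sample at 2x
  dff <- compute_dff(raw)
  expect_equal(dff$samples[100], 1.0)

  # random trace vs an independent elementwise oracle
  set.seed(4)
  v <- runif(501, 50, 150)
  d2 <- compute_dff(nl_trace(v, fs = 10))
  fm <- sort(v)[251]
  expect_equal(d2$samples, (v - fm) / fm, tolerance = 1e-12)

  # scale invariance: dF/F unchanged under positive rescaling of raw
  d3 <- compute_dff(nl_trace(3.7 * v, fs = 10))
  expect_equal(d3$samples, d2$samples, tolerance = 1e-12)

  # pre-stimulus mode uses the 10 s window before the event
  tr <- nl_trace(c(rep(10, 100), rep(20, 100)), fs = 10)
  dp <- compute_dff(tr, "pre_stimulus", event_time = 10, pre_window = 10)
  expect_equal(dp$samples[150], 1.0)

  expect_error(compute_dff(nl_trace(c(-1, 0, 1, 0, 0), fs = 1)),
               class = "nremlink_degenerate_baseline")
})

test_that("detrend_baseline removes a quadratic exactly and passes short traces", {
  fs <- 20
  t <- seq(0, 700, by = 1 / fs)
  quad <- 100 + 0.01 * t - 1e-5 * t^2
  out <- detrend_baseline(nl_trace(quad, fs = fs), degree = 2)
  expect_lt(max(out$samples) - min(out$samples), 1e-9 * (max(quad) - min(quad)))

  short <- nl_trace(quad[1:100], fs = fs)
  expect_identical(detrend_baseline(short, 2)$samples, short$samples)

  const <- nl_trace(rep(5, 700 * fs), fs = fs)
  expect_equal(detrend_baseline(const, 2)$samples, const$samples,
               tolerance = 1e-12)
})

test_that("detrending preserves planted transient amplitudes within 5%", {
  fx <- fx_sleep()
  cfg <- fx$cfg
  detr <- detrend_baseline(fx$photo, 2)
  # oracle: subtract the known drift polynomial instead of the fitted one
  t <- (seq_along(fx$photo$samples) - 1) / fx$photo$fs
  oracle <- fx$photo$samples - nremlink:::polyval(cfg$drift_coeffs, t)
  idx <- round(fx$events$peak_time * fx$photo$fs) + 1
  idx <- idx[idx <= length(t)]
  expect_equal(detr$samples[idx] - median(detr$samples),
               oracle[idx] - median(oracle),
               tolerance = 0.05)
})

test_that("find_quiet_period returns the flattest NREM window", {
  fs <- 20
  hyp <- hypnogram(rep(c("Wake", "NREM", "NREM", "Wake"), each = 60),
                   epoch_len = 5)   # 300 s Wake, 600 s NREM, 300 s Wake
  set.seed(5)
  x <- rnorm(1200 * fs, sd = 1)
  # one flat NREM stretch: 350-600 s
  flat <- (350 * fs):(600 * fs)
  x[flat] <- rnorm(length(flat), sd = 0.01)
  dff <- nl_trace(x, fs = fs)
  qp <- find_quiet_period(dff, hyp, length = 250)
  expect_gte(qp$start, 345)
  expect_lte(qp$end, 605)
  expect_equal(qp$end - qp$start, 250, tolerance = 2 / fs)
  expect_lt(qp$sd, 0.02)
  expect_error(
    find_quiet_period(dff, hypnogram(rep("Wake", 240), epoch_len = 5), 250),
    class = "nremlink_insufficient_data")
})

test_that("detect_transients matches the brute-force oracle on varied traces", {
  fs <- 20
  gauss_bump <- function(center, width, amp, t) amp * exp(-((t - center)^2) / (2 * width^2))
  t <- seq(0, 200 - 1 / fs, by = 1 / fs)
  traces <- list()
  set.seed(11)
  traces$bumps <- gauss_bump(50, 2, 1, t) + gauss_bump(120, 3, 0.6, t) +
    rnorm(length(t), sd = 0.01)
  traces$walk <- cumsum(rnorm(4000, sd = 0.05))
  traces$noise <- rnorm(4000, sd = 0.2)
  traces$sine_spikes <- sin(2 * pi * 0.02 * t) * 0.5 +
    gauss_bump(30, 1.2, 2, t) + gauss_bump(90, 0.3, 2, t) +
    rnorm(length(t), sd = 0.02)
  for (nm in names(traces)) {
    x <- traces[[nm]]
    qsd <- 0.05
    got <- detect_transients(nl_trace(x, fs = fs), qsd)
    exp_df <- oracle_detect(x, fs, qsd)
    if (is.null(exp_df)) {
      expect_equal(nrow(got), 0, info = nm)
    } else {
      expect_equal(nrow(got), nrow(exp_df), info = nm)
      expect_equal(got$peak_time, (exp_df$peak - 1) / fs, info = nm)
      expect_equal(got$amplitude, exp_df$prominence, tolerance = 1e-12, info = nm)
      expect_equal(got$half_width, exp_df$half_width, tolerance = 1e-9, info = nm)
    }
  }
})

test_that("detection anchors: flat trace, wide bump kept, narrow bump filtered", {
  fs <- 20
  expect_equal(nrow(detect_transients(nl_trace(rep(0, 1000), fs = fs), 0.1)), 0)
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  wide <- 0.5 * exp(-((t - 30)^2) / (2 * (3 / 2.355)^2))   # FWHM 3 s
  got <- detect_transients(nl_trace(wide, fs = fs), 0.1 / 5)  # prom 5x quiet sd
  expect_equal(nrow(got), 1)
  expect_equal(got$peak_time, 30, tolerance = 1 / fs)
  narrow <- 0.5 * exp(-((t - 30)^2) / (2 * (0.5 / 2.355)^2)) # FWHM 0.5 s
  expect_equal(nrow(detect_transients(nl_trace(narrow, fs = fs), 0.1 / 5)), 0)
  expect_error(detect_transients(nl_trace(wide, fs = fs), 0),
               class = "nremlink_invalid_argument")
})

test_that("transient extents never overlap and state counts partition totals", {
  fx <- fx_sleep()
  dff <- smooth_trace(compute_dff(detrend_baseline(fx$photo, 2)))
  qp <- find_quiet_period(dff, fx$hyp, 250)
  tr <- detect_transients(dff, qp$sd)
  expect_true(all(tr$half_width >= 1.5))
  if (nrow(tr) > 1) expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)] - 1e-9))
  summ <- state_activity_summary(tr, dff, fx$hyp)
  expect_equal(sum(summ$n_transients), nrow(tr))
  expect_true(all(summ$cumulative_integral >= 0))
})

test_that("state_activity_summary handles empty and single-state cases", {
  dff <- nl_trace(rep(0, 1200), fs = 10)
  hyp <- hypnogram(rep("REM", 24), epoch_len = 5)
  empty <- detect_transients(dff, 0.1)
  s0 <- state_activity_summary(empty, dff, hyp)
  expect_true(all(s0$n_transients == 0))
  expect_true(all(s0$cumulative_integral == 0))

  tr <- data.frame(peak_time = c(10, 50), amplitude = c(1, 1),
                   half_width = c(2, 2), start = c(8, 48), end = c(12, 52))
  s1 <- state_activity_summary(tr, dff, hyp)
  expect_equal(s1$n_transients[s1$state == "NREM"], 0)
  expect_equal(s1$n_transients[s1$state == "REM"], 2)
  expect_error(state_activity_summary(tr, dff, hypnogram(character(0))),
               class = "nremlink_error")
})

test_that("round-trip recovery: >= 90% sensitivity, <= 10% FDR at defaults", {
  hits <- c(); fds <- c()
  for (s in 1:5) {
    cfg <- sim_config_desk(seed = s)
    hyp <- simulate_hypnogram(cfg, 1800, seed = s)
    ph <- synth_photometry(hyp, cfg, seed = s + 100)
    dff <- smooth_trace(compute_dff(detrend_baseline(ph$trace, 2)))
    qp <- find_quiet_period(dff, hyp, 250)
    tr <- detect_transients(dff, qp$sd)
    big <- ph$events$amplitude >= 5 * cfg$noise_sd
    hit <- vapply(ph$events$peak_time[big], function(tp)
      any(abs(tr$peak_time - tp) <= 0.5), logical(1))
    fd <- vapply(tr$peak_time, function(tp)
      !any(abs(ph$events$peak_time - tp) <= 0.5), logical(1))
    hits <- c(hits, hit); fds <- c(fds, fd)
  }
  expect_gte(mean(hits), 0.9)
  expect_lte(mean(fds), 0.1)
})

test_that("standardize_across_animals matches the closed-form oracle", {
  df <- data.frame(mouse = rep(1:2, each = 4), day = rep(1:4, 2),
                   mean_amplitude = c(1, 2, 3, 4, 5, 3, 8, 2))
  out <- standardize_across_animals(df)
  # oracle: z-score then OLS residuals, by hand per mouse
  for (m in 1:2) {
    v <- df$mean_amplitude[df$mouse == m]
    z <- (v - mean(v)) / sd(v)
    d <- 1:4
    beta <- sum((d - mean(d)) * (z - mean(z))) / sum((d - mean(d))^2)
    resid <- z - (mean(z) + beta * (d - mean(d)))
    expect_equal(out$standardized[out$mouse == m], resid, tolerance = 1e-12)
    expect_equal(mean(out$standardized[out$mouse == m]), 0, tolerance = 1e-12)
  }
  # exact linear day trend -> residuals ~ 0
  lin <- data.frame(mouse = 1, day = 1:5, mean_amplitude = 2 + 3 * (1:5))
  expect_equal(standardize_across_animals(lin)$standardized, rep(0, 5),
               tolerance = 1e-10)
  expect_error(standardize_across_animals(
    data.frame(mouse = 1, day = 1, mean_amplitude = 1)),
    class = "nremlink_insufficient_data")
})

test_that("align_to_events averages snippets and drops partial windows", {
  const <- nl_trace(rep(2, 1000), fs = 10)
  dff <- compute_dff(const)   # zeros
  al <- align_to_events(dff, c(20, 50, 80), window = c(1, 2))
  expect_true(all(al$mean == 0))
  expect_true(all(al$sem == 0))

  one <- align_to_events(dff, 50, window = c(1, 1))
  expect_equal(one$mean, as.numeric(one$snippets[1, ]))

  # planted step at each event: mean shows the step; SEM shrinks ~ 1/sqrt(n)
  set.seed(3)
  fs <- 10
  x <- rnorm(60000, sd = 0.3)
  ev <- seq(50, 5950, by = 59)
  for (e in ev) x[(e * fs):(e * fs + 5 * fs)] <- x[(e * fs):(e * fs + 5 * fs)] + 1
  tr <- nl_trace(x, fs = fs)
  al2 <- align_to_events(tr, ev, window = c(1, 2))
  pre <- al2$time < 0; post <- al2$time > 0.2
  expect_gt(mean(al2$mean[post]) - mean(al2$mean[pre]), 0.8)
  expect_lt(mean(al2$sem), 2 * 0.3 / sqrt(length(ev)))

  expect_warning(align_to_events(dff, c(0.01, 50), window = c(1, 1)),
                 "dropped")
  expect_error(suppressWarnings(align_to_events(dff, 1e6, window = c(1, 1))),
               class = "nremlink_insufficient_data")
})
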