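# Port-zone visits, visit speed, speed mixture, pod visits, trial metrics,
# novelty preference, occupancy maps.

test_that("nose_speed: stationary, linear and circular motion", {
  still <- make_still_traj(0, 0, n = 30)
  expect_true(all(nose_speed(still) < 1e-9))

  lin <- make_path_traj(list(c(0, 0, 0), c(60, 0, 12)))
  sp <- nose_speed(lin, smoothing = 1)
  inner <- sp[3:(length(sp) - 2)]
  expect_true(all(abs(inner - 12) < 1e-9))

  # circular motion radius r, angular rate w -> speed r*w within 2%
  fs <- 10; r <- 10; w <- 1
  t <- seq(0, 10, by = 1 / fs)
  pts <- cbind(r * cos(w * t), r * sin(w * t))
  traj <- trajectory(time = t, nose = pts, center = pts, tail = pts,
                     area = rep(12, length(t)), fs = fs)
  sp2 <- nose_speed(traj, smoothing = 1)
  inner2 <- sp2[3:(length(sp2) - 2)]
  expect_true(all(abs(inner2 - r * w) / (r * w) < 0.02))

  expect_error(nose_speed(make_still_traj(0, 0, n = 1)),
               class = "nremlink_invalid_argument")
})

test_that("detect_port_entries applies the zone predicate and merge rule", {
  geom <- maze_geometry()
  # radial pass through the port-1 zone (bearing 0 degrees)
  pass <- make_path_traj(list(c(30, 0, 0), c(54, 0, 10), c(30, 0, 10)))
  vis <- detect_port_entries(pass, geom)
  expect_equal(nrow(vis), 1)
  expect_equal(vis$port, 1)
  # entry frame satisfies the predicate exactly
  ef <- which(abs(pass$time - vis$entry_time) < 1e-9)
  rr <- sqrt(sum(pass$nose[ef, ]^2))
  expect_true(rr >= geom$zone_r[1] && rr <= geom$zone_r[2])

  # confined to radius 40: no visits
  inner <- make_path_traj(list(c(0, 0, 0), c(38, 0, 10), c(0, 30, 10)))
  expect_equal(nrow(detect_port_entries(inner, geom)), 0)

  # two crossings separated by an out-of-zone stretch: frame-exact control of
  # the gap via explicit nose x-coordinates (zone spans x in [50, 58])
  mk_crossings <- function(gap_frames) {
    x <- c(rep(54, 5), rep(47, gap_frames), rep(54, 5))
    pts <- cbind(x, 0)
    n <- nrow(pts)
    trajectory(time = (seq_len(n) - 1) / 10, nose = pts, center = pts,
               tail = pts, area = rep(12, n), fs = 10)
  }
  expect_equal(nrow(detect_port_entries(mk_crossings(30), geom)), 2)  # 3 s out
  expect_equal(nrow(detect_port_entries(mk_crossings(3), geom)), 1)   # 0.3 s
})

test_that("port_visit_speed averages the -0.5/+2.5 s window", {
  # constant 9 cm/s: x advances exactly 0.9 cm per frame
  n <- 130
  pts <- cbind(0.9 * (seq_len(n) - 1), 0)
  lin <- trajectory(time = (seq_len(n) - 1) / 10, nose = pts, center = pts,
                    tail = pts, area = rep(12, n), fs = 10)
  expect_equal(port_visit_speed(lin, entry_time = 5), 9, tolerance = 1e-9)

  # two-level speed series: expected value by direct frame enumeration
  spd <- c(rep(4, 30), rep(12, 100))   # 4 cm/s for t < 3 s, then 12
  idx <- which(lin$time >= 1.5 - 1e-9 & lin$time <= 4.5 + 1e-9)
  expected <- mean(spd[idx])           # 15 frames at 4, 16 at 12
  expect_equal(expected, (15 * 4 + 16 * 12) / 31)
  expect_equal(port_visit_speed(lin, entry_time = 2, speed = spd), expected)

  still <- make_still_traj(0, 0, n = 60)
  expect_equal(port_visit_speed(still, 2), 0, tolerance = 1e-9)

  # truncated window -> NA (unassigned)
  expect_true(is.na(port_visit_speed(still, 0.2)))
  expect_true(is.na(port_visit_speed(still, 5.8)))
})

test_that("fit_speed_mixture recovers planted components and selects k by BIC", {
  set.seed(1)
  x <- c(rnorm(100, 5, 1), rnorm(100, 25, 2))
  m <- fit_speed_mixture(x)
  expect_equal(m$selected_k, 2)
  expect_equal(m$means[1], 5, tolerance = 1 / 5)
  expect_equal(m$means[2], 25, tolerance = 1 / 25)
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
  expect_true(all(m$assignment[x < 10] == "slow"))
  expect_true(all(m$assignment[x > 20] == "fast"))

  k1 <- vapply(1:50, function(s) {
    set.seed(s); fit_speed_mixture(rnorm(200, 10, 2))$selected_k
  }, numeric(1))
  expect_gte(mean(k1 == 1), 0.9)

  expect_error(fit_speed_mixture(rnorm(10)), class = "nremlink_insufficient_data")
  expect_error(fit_speed_mixture(rep(5, 30)),
               class = "nremlink_insufficient_variance")
})

test_that("mixture assignment agrees with generator motifs for wide separation", {
  cfg <- sim_config_desk()
  speeds <- c(); motifs <- c()
  for (s in 1:25) {
    tr <- synth_maze_session(0, cfg, seed = 500 + s)
    g <- attr(tr, "geometry")
    vis <- detect_port_entries(tr, g)
    gt <- attr(tr, "visits")
    if (is.null(gt) || !nrow(gt)) next
    for (i in seq_len(nrow(gt))) {
      j <- which.min(abs(vis$entry_time - gt$entry_time[i]))
      if (length(j) && abs(vis$entry_time[j] - gt$entry_time[i]) <= 0.5 &&
            !is.na(vis$visit_speed[j])) {
        speeds <- c(speeds, vis$visit_speed[j])
        motifs <- c(motifs, gt$motif[i])
      }
    }
  }
  m <- fit_speed_mixture(speeds)
  expect_equal(m$selected_k, 2)
  expect_gte(mean(m$assignment == motifs), 0.9)
  # planted motif means recovered within 10% each
  expect_equal(mean(speeds[motifs == "slow"]), cfg$slow_speed_mu,
               tolerance = 0.1)
  expect_equal(mean(speeds[motifs == "fast"]), cfg$fast_speed_mu,
               tolerance = 0.1)
})

test_that("correct_pod_visits counts entries and retreats per the rules", {
  geom <- maze_geometry()   # correct port 1 at bearing 0; pod center (60, 0)
  # nose x-coordinate series along the port bearing (y = 0); pod perimeter
  # is x in [57, 63], door line x > 58
  mk <- function(xs) {
    pts <- cbind(xs, 0)
    n <- nrow(pts)
    trajectory(time = (seq_len(n) - 1) / 10, nose = pts, center = pts,
               tail = pts, area = rep(12, n), fs = 10)
  }
  approach <- seq(30, 57, by = 1)
  # approach ending inside the pod (nose crosses the door line)
  entry <- mk(c(approach, 58.5, 59.5, rep(59.5, 8)))
  expect_equal(correct_pod_visits(entry, geom),
               list(with_entry = 1L, without_entry = 0L))

  # approach to 2 cm from the pod (x = 58 exactly is still on the door line
  # boundary, not past it) then retreat to 10 cm
  retreat <- mk(c(approach, 57.8, 57.8, seq(57, 50, by = -1), seq(49, 30, by = -2)))
  expect_equal(correct_pod_visits(retreat, geom),
               list(with_entry = 0L, without_entry = 1L))

  # three approach-retreat cycles then an entry
  cycle <- c(57.5, 57.5, 55, 52)
  cyc <- mk(c(approach, rep(cycle, 3), 57.5, 58.5, 59.5, rep(59.5, 5)))
  out <- correct_pod_visits(cyc, geom)
  expect_equal(out$with_entry, 1L)
  expect_equal(out$without_entry, 3L)
})

test_that("trial_metrics: path length, normalization and references", {
  geom <- maze_geometry()
  # entry fires when the nose (center + 2 cm) passes the 58 cm door line,
  # i.e. center x = 56; starting at x = 6 the path to entry is 50 cm
  straight <- make_path_traj(list(c(6, 0, 0), c(58.5, 0, 10)))
  m <- trial_metrics(straight, geom, reference_trial = straight)
  expect_equal(m$distance_to_escape, 50, tolerance = 0.01)
  expect_equal(m$normalized_distance, 1.0)
  expect_true(m$escaped)

  # sawtooth of known segment lengths (no pod entry: full path counted)
  saw <- make_path_traj(list(c(0, 0, 0), c(10, 0, 10), c(10, 8, 10),
                             c(20, 8, 10), c(20, 0, 10)))
  ms <- trial_metrics(saw, geom)
  expect_equal(ms$distance_to_escape, 36, tolerance = 0.02)
  expect_false(ms$escaped)

  expect_error(trial_metrics(straight, geom,
                             reference_trial = make_still_traj(0, 0)),
               class = "nremlink_invalid_reference")
})

test_that("novelty_preference implements the ratio with planted dwell times", {
  objects <- rbind(c(-25, 0), c(25, 0))
  frames <- function(obj, n) {
    matrix(rep(objects[obj, ] + c(1, 0), each = n), ncol = 2)
  }
  # 90 s novel / 30 s familiar at 10 Hz
  nose <- rbind(frames(1, 900), matrix(rep(c(0, 30), each = 200), ncol = 2),
                frames(2, 300))
  n <- nrow(nose)
  traj <- trajectory(time = (seq_len(n) - 1) / 10, nose = nose, center = nose,
                     tail = nose, area = rep(12, n), fs = 10)
  expect_equal(novelty_preference(traj, objects), 0.75)
  # equal dwell -> 0.5 (chance level); novel only -> 1
  nose_eq <- rbind(frames(1, 300), frames(2, 300))
  traj_eq <- trajectory(time = (seq_len(600) - 1) / 10, nose = nose_eq,
                        center = nose_eq, tail = nose_eq,
                        area = rep(12, 600), fs = 10)
  expect_equal(novelty_preference(traj_eq, objects), 0.5)
  nose_nov <- frames(1, 300)
  traj_nov <- trajectory(time = (seq_len(300) - 1) / 10, nose = nose_nov,
                         center = nose_nov, tail = nose_nov,
                         area = rep(12, 300), fs = 10)
  expect_equal(novelty_preference(traj_nov, objects), 1.0)
  far <- make_still_traj(0, 0, n = 50)
  expect_error(novelty_preference(far, objects),
               class = "nremlink_undefined_ratio")
})

test_that("occupancy_map conserves time and localizes dwell", {
  geom <- maze_geometry()
  still <- make_still_traj(10, -5, n = 80)
  m <- occupancy_map(still, geom, bin = 5)
  expect_equal(sum(m), 8)                  # 80 frames / 10 Hz
  expect_equal(sum(m > 0), 1)              # single bin

  tr <- synth_maze_session(0, sim_config_desk(), seed = 4)
  m2 <- occupancy_map(tr, attr(tr, "geometry"), bin = 5)
  expect_equal(sum(m2), length(tr$time) / tr$fs, tolerance = 1e-9)

  # uniform circular sweep: near-uniform ring occupancy
  fs <- 10
  t <- seq(0, 120, by = 1 / fs)
  ring <- cbind(40 * cos(0.5 * t), 40 * sin(0.5 * t))
  rt <- trajectory(time = t, nose = ring, center = ring, tail = ring,
                   area = rep(12, length(t)), fs = fs)
  m3 <- occupancy_map(rt, geom, bin = 10)
  occ <- m3[m3 > 0.2]
  expect_lt(sd(occ) / mean(occ), 0.3)
})
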