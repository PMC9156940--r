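# Synthetic maze and object-arena trajectory generators, plus the multi-day
# experiment assembler that plants the sleep-to-behavior coupling.

# Walk from `pos` toward `target` at speed v (cm/s), one row per frame,
# excluding the start position. Returns a matrix (possibly 0-row).
path_walk <- function(pos, target, v, fs, jitter = 0.15) {
  d <- sqrt(sum((target - pos)^2))
  n_steps <- max(1L, as.integer(round(d / (v / fs))))
  fr <- seq_len(n_steps) / n_steps
  out <- cbind(pos[1] + fr * (target[1] - pos[1]),
               pos[2] + fr * (target[2] - pos[2]))
  out + matrix(stats::rnorm(2 * n_steps, sd = jitter), ncol = 2)
}

polar_xy <- function(r, ang_deg) {
  a <- ang_deg * pi / 180
  c(r * cos(a), r * sin(a))
}

# sample a port index with geometric concentration around the correct port
sample_port <- function(geom, bias) {
  k <- geom$n_ports
  dists <- pmin(abs(seq_len(k) - geom$correct_port),
                k - abs(seq_len(k) - geom$correct_port))
  w <- (1 - bias)^dists
  sample.int(k, 1, prob = w / sum(w))
}

#' Simulate one maze trial trajectory
#'
#' Produces a 10 Hz nose/center/tail/area trajectory inside the circular
#' arena.  The trajectory alternates locomotion segments between random
#' waypoints, brief pauses, and port approaches.  Each port visit is drawn
#' slow (investigative; target nose speed ~ Normal(`slow_speed_mu`,
#' `speed_sd`)) or fast (pass-and-go; ~ Normal(`fast_speed_mu`, `speed_sd`))
#' with P(slow) = logistic(`drive`); the visit-speed window (-0.5 s to
#' +2.5 s around zone entry) is traversed at the drawn speed.  Visited ports
#' concentrate geometrically around the correct port (spatial memory); the
#' trial always ends with the nose entering the correct escape pod.
#'
#' @param drive real; slow-visit log-odds. `drive = 0` gives 50/50 motifs.
#' @param config a [sim_config()].
#' @param trial_duration soft cap in seconds on trial length (must allow at
#'   least one visit, >= 12 s).
#' @param seed integer seed.
#' @param correct_port index of the open port.
#' @return a [trajectory()]; `attr(, "visits")` is the ground-truth visit
#'   table (`port`, `motif`, `target_speed`, `entry_time`),
#'   `attr(, "geometry")` the [maze_geometry()] used.
#' @export
synth_maze_session <- function(drive, config, trial_duration = config$trial_duration,
                               seed = config$seed, correct_port = 1L) {
  nl_assert(trial_duration >= 12,
            "trial_duration too short to contain one port visit")
  geom <- maze_geometry(arena_diameter = config$arena_diameter,
                        n_ports = config$n_ports,
                        correct_port = correct_port)
  fs <- config$track_fs
  r_in <- geom$zone_r[1]
  with_seed(seed, {
    pts <- matrix(c(stats::rnorm(2, sd = 0.5)), ncol = 2)  # start near center
    fh <- matrix(NA_real_, 1, 2)  # fixed nose heading (NA = from displacement)
    visits <- list()
    n_extra <- stats::rpois(1, max(0, config$visits_per_trial - 1))
    total_planned <- n_extra + 1L

    add <- function(seg, heading = NULL) {
      pts <<- rbind(pts, seg)
      h <- if (is.null(heading)) matrix(NA_real_, nrow(seg), 2) else
        matrix(heading, nrow(seg), 2, byrow = TRUE)
      fh <<- rbind(fh, h)
    }
    cur <- function() pts[nrow(pts), ]
    t_now <- function() (nrow(pts) - 1) / fs

    for (vi in seq_len(total_planned)) {
      final <- vi == total_planned
      if (!final && t_now() > trial_duration - 15) next
      port <- if (final) geom$correct_port else sample_port(geom, config$port_bias)
      bearing <- geom$port_angles[port]
      u_port <- polar_xy(1, bearing)
      slow <- stats::runif(1) < stats::plogis(drive)
      mu <- if (slow) config$slow_speed_mu else config$fast_speed_mu
      v <- max(1, stats::rnorm(1, mu, config$speed_sd))

      # wander toward the port side of the arena, sometimes pausing
      wp <- polar_xy(stats::runif(1, 10, 38),
                     bearing + stats::rnorm(1, 0, 40))
      add(path_walk(cur(), wp, max(5, stats::rnorm(1, 15, 3)), fs))
      if (stats::runif(1) < 0.3) {
        n_pause <- round(fs * stats::runif(1, 0.8, 2))
        add(matrix(rep(cur(), each = n_pause), ncol = 2) +
              matrix(stats::rnorm(2 * n_pause, sd = 0.1), ncol = 2))
      }
      # approach at ordinary locomotion speed until ~1.2 s before zone entry,
      # then run the visit window at the drawn motif speed (the drive must
      # touch only the port-visit window, not overall locomotion)
      r_run <- max(15, r_in - 2 - 1.2 * v)
      a0 <- polar_xy(r_run, bearing + stats::rnorm(1, 0, 2))
      add(path_walk(cur(), a0, max(5, stats::rnorm(1, 15, 3)), fs))
      t_entry <- t_now() + (r_in - 2 - r_run) / v  # nose crosses zone_r_in
      add(path_walk(cur(), polar_xy(r_in + 2, bearing), v, fs, jitter = 0.05),
          heading = u_port)
      if (final) {
        # escape: cross the pod door line (nose beyond zone_r_outer within
        # the wedge, inside the pod perimeter), then sit in the pod
        add(path_walk(cur(), polar_xy(geom$zone_r[2] + 0.5, bearing), v, fs,
                      jitter = 0.03), heading = u_port)
        n_hold <- round(fs * 1.5)
        add(matrix(rep(cur(), each = n_hold), ncol = 2) +
              matrix(stats::rnorm(2 * n_hold, sd = 0.02), ncol = 2),
            heading = u_port)
      } else if (slow) {
        # investigation: slow radial bobbing inside the zone, nose kept
        # pointed at the port, for ~3 s (covers the visit-speed window)
        t_done <- t_now() + 3
        sgn <- 1
        while (t_now() < t_done) {
          rr <- if (sgn > 0) r_in + 3.5 else r_in + 0.5
          add(path_walk(cur(), polar_xy(rr, bearing + stats::rnorm(1, 0, 1)),
                        v, fs, jitter = 0.05), heading = u_port)
          sgn <- -sgn
        }
        add(path_walk(cur(), polar_xy(30, bearing + stats::rnorm(1, 0, 10)),
                      max(5, stats::rnorm(1, 15, 3)), fs))
      } else {
        # pass-and-go: sweep out of the zone, still at the visit speed,
        # long enough to cover the -0.5/+2.5 s speed window
        out1 <- polar_xy(30, bearing + sample(c(-25, 25), 1))
        add(path_walk(cur(), out1, v, fs, jitter = 0.05))
        t_done <- t_entry + 2.8
        while (t_now() < t_done) {
          add(path_walk(cur(), polar_xy(stats::runif(1, 15, 35),
                                        bearing + stats::rnorm(1, 0, 40)),
                        v, fs))
        }
      }
      if (!final) {
        visits[[length(visits) + 1]] <- data.frame(
          port = port, motif = if (slow) "slow" else "fast",
          target_speed = v, entry_time = t_entry)
      }
    }

    n <- nrow(pts)
    # clamp center inside the arena (jitter can graze the wall)
    rr <- sqrt(rowSums(pts^2))
    over <- rr > arena_radius(geom) - 0.5
    if (any(over)) pts[over, ] <- pts[over, ] * (arena_radius(geom) - 0.5) / rr[over]

    # heading from smoothed displacement, overridden where a fixed heading
    # was laid down (nose pointed at a port during investigation/escape)
    dx <- boxcar(c(diff(pts[, 1]), 0), 3)
    dy <- boxcar(c(diff(pts[, 2]), 0), 3)
    nrm <- sqrt(dx^2 + dy^2)
    still <- nrm < 1e-6
    dx[still] <- 1; dy[still] <- 0; nrm[still] <- 1
    u <- cbind(dx / nrm, dy / nrm)
    fixed <- !is.na(fh[, 1])
    u[fixed, ] <- fh[fixed, , drop = FALSE]
    nose <- pts + 2 * u + matrix(stats::rnorm(2 * n, sd = 0.05), ncol = 2)
    tail <- pts - 2 * u + matrix(stats::rnorm(2 * n, sd = 0.05), ncol = 2)
    area <- 12 + stats::rnorm(n, sd = 0.4)
    traj <- trajectory(time = (seq_len(n) - 1) / fs, nose = nose,
                       center = pts, tail = tail, area = area, fs = fs)
  })
  attr(traj, "visits") <- do.call(rbind, visits)
  attr(traj, "geometry") <- geom
  traj
}

#' Simulate a novel-object session
#'
#' Nose/center/tail trajectory in the arena with two object locations; the
#' animal alternates wandering with object-investigation bouts.  Each bout
#' targets the novel object with probability `preference` and dwells with the
#' nose inside the object's 2 cm exploration perimeter for a fixed 4 s, so
#' the expected fraction of object-zone dwell time at the novel object equals
#' `preference`.
#'
#' @param preference probability in `[0, 1]` that an investigation bout
#'   targets the novel object.
#' @param config a [sim_config()].
#' @param duration session length, seconds.
#' @param seed integer seed.
#' @return a [trajectory()]; `attr(, "objects")` is a 2 x 2 matrix of object
#'   centers (row 1 = novel, row 2 = familiar).
#' @export
synth_object_session <- function(preference, config, duration = 600,
                                 seed = config$seed) {
  nl_assert(preference >= 0 && preference <= 1,
            "preference must be in [0, 1]")
  fs <- config$track_fs
  objects <- rbind(novel = c(-25, 0), familiar = c(25, 0))
  with_seed(seed, {
    pts <- matrix(stats::rnorm(2, sd = 1), ncol = 2)
    dwell_obj <- integer(1)  # per-frame: object being investigated (0 = none)
    n_target <- round(duration * fs)
    while (nrow(pts) < n_target) {
      # wander
      wp <- polar_xy(stats::runif(1, 5, 40), stats::runif(1, 0, 360))
      seg <- path_walk(pts[nrow(pts), ], wp, max(5, stats::rnorm(1, 14, 3)), fs)
      pts <- rbind(pts, seg); dwell_obj <- c(dwell_obj, integer(nrow(seg)))
      if (nrow(pts) >= n_target) break
      # object investigation bout
      which_obj <- if (stats::runif(1) < preference) 1L else 2L
      obj <- objects[which_obj, ]
      appr_ang <- stats::runif(1, 0, 2 * pi)
      stand <- obj + 3.5 * c(cos(appr_ang), sin(appr_ang))
      seg <- path_walk(pts[nrow(pts), ], stand,
                       max(5, stats::rnorm(1, 14, 3)), fs)
      pts <- rbind(pts, seg); dwell_obj <- c(dwell_obj, integer(nrow(seg)))
      n_dwell <- round(4 * fs)
      pts <- rbind(pts, matrix(rep(stand, each = n_dwell), ncol = 2) +
                     matrix(stats::rnorm(2 * n_dwell, sd = 0.03), ncol = 2))
      dwell_obj <- c(dwell_obj, rep(which_obj, n_dwell))
    }
    pts <- pts[seq_len(n_target), , drop = FALSE]
    dwell_obj <- dwell_obj[seq_len(n_target)]
    n <- nrow(pts)
    dx <- boxcar(c(diff(pts[, 1]), 0), 3)
    dy <- boxcar(c(diff(pts[, 2]), 0), 3)
    nrm <- sqrt(dx^2 + dy^2)
    # while dwelling, the nose points at the nearest object
    still <- nrm < 0.5 / fs
    if (any(still)) {
      d1 <- sqrt(rowSums((pts - matrix(objects[1, ], n, 2, byrow = TRUE))^2))
      d2 <- sqrt(rowSums((pts - matrix(objects[2, ], n, 2, byrow = TRUE))^2))
      tgt <- ifelse(d1 < d2, 1L, 2L)
      vx <- objects[tgt, 1] - pts[, 1]; vy <- objects[tgt, 2] - pts[, 2]
      vn <- sqrt(vx^2 + vy^2); vn[vn == 0] <- 1
      dx[still] <- vx[still] / vn[still]
      dy[still] <- vy[still] / vn[still]
      nrm[still] <- 1
    }
    u <- cbind(dx / nrm, dy / nrm)
    nose <- pts + 2 * u + matrix(stats::rnorm(2 * n, sd = 0.03), ncol = 2)
    # exploration is intentional: outside investigation bouts the nose keeps
    # clear of the object perimeters (incidental grazes would otherwise count
    # as exploration and blur the planted preference)
    per <- 2
    for (j in 1:2) {
      dxo <- nose[, 1] - objects[j, 1]; dyo <- nose[, 2] - objects[j, 2]
      dd <- sqrt(dxo^2 + dyo^2)
      fixup <- dwell_obj != j & dd < per + 0.3
      if (any(fixup)) {
        scale <- (per + 0.5) / pmax(dd[fixup], 1e-6)
        nose[fixup, 1] <- objects[j, 1] + dxo[fixup] * scale
        nose[fixup, 2] <- objects[j, 2] + dyo[fixup] * scale
      }
    }
    tail <- pts - 2 * u + matrix(stats::rnorm(2 * n, sd = 0.03), ncol = 2)
    traj <- trajectory(time = (seq_len(n) - 1) / fs, nose = nose, center = pts,
                       tail = tail, area = 12 + stats::rnorm(n, sd = 0.4),
                       fs = fs)
  })
  attr(traj, "objects") <- objects
  traj
}

#' Generate a full multi-day, multi-mouse synthetic experiment
#'
#' For every mouse x day: a home-cage rest recording (hypnogram, optionally
#' raw EEG/EMG and photometry) and a set of maze trials.  The slow-visit
#' log-odds (drive) of day `d`'s trials equals `coupling` times the
#' ground-truth standardized NREM transient amplitude of the *preceding*
#' day's rest (day-1 trials get drive 0), planting the next-day
#' sleep-to-behavior link the correlation layer is designed to recover.
#' Standardization is the same within-mouse z-score + across-day linear
#' detrend applied to measured data by [standardize_across_animals()].
#'
#' @param config a [sim_config()].
#' @param include_raw generate raw EEG/EMG and photometry traces (set
#'   `FALSE` for fast runs that only need ground truth and trajectories).
#' @return list with `rests` (per mouse-day: `mouse`, `day`, `hypnogram`,
#'   `photometry` (`trace` + `events`), `eeg`, `emg`), `trials` (list of
#'   [trajectory()] objects with visit ground truth), and `ground_truth`
#'   (`coupling`, `nrem_activity` per mouse-day with `standardized` column,
#'   `drive`, pooled `visits` table).
#' @export
synth_multiday_experiment <- function(config, include_raw = TRUE) {
  seed <- config$seed
  rests <- list(); trials <- list()
  amp_tab <- NULL
  for (m in seq_len(config$n_mice)) {
    for (d in seq_len(config$n_days)) {
      hyp <- simulate_hypnogram(config, config$rest_duration,
                                seed = derive_seed(seed, m, d, 1))
      photo <- synth_photometry(hyp, config, seed = derive_seed(seed, m, d, 2))
      raw <- if (include_raw) {
        synth_eeg_emg(hyp, config, seed = derive_seed(seed, m, d, 3))
      } else list(eeg = NULL, emg = NULL)
      nrem_amps <- photo$events$amplitude[photo$events$state == "NREM"]
      amp_tab <- rbind(amp_tab, data.frame(
        mouse = m, day = d,
        mean_amp = if (length(nrem_amps)) mean(nrem_amps) else 0))
      rests[[length(rests) + 1]] <- list(
        mouse = m, day = d, hypnogram = hyp,
        photometry = if (include_raw) photo$trace else NULL,
        events = photo$events, eeg = raw$eeg, emg = raw$emg)
    }
  }
  amp_tab$standardized <- standardize_values(amp_tab$mouse, amp_tab$day,
                                             amp_tab$mean_amp)
  drive_tab <- amp_tab[, c("mouse", "day")]
  drive_tab$drive <- 0
  for (i in seq_len(nrow(drive_tab))) {
    if (drive_tab$day[i] > 1) {
      prev <- amp_tab$standardized[amp_tab$mouse == drive_tab$mouse[i] &
                                     amp_tab$day == drive_tab$day[i] - 1]
      drive_tab$drive[i] <- config$coupling * prev
    }
  }
  visit_tab <- NULL
  for (m in seq_len(config$n_mice)) {
    correct <- ((m - 1L) %% config$n_ports) + 1L
    for (d in seq_len(config$n_days)) {
      drv <- drive_tab$drive[drive_tab$mouse == m & drive_tab$day == d]
      for (tr in seq_len(config$trials_per_day)) {
        traj <- synth_maze_session(drv, config,
                                   seed = derive_seed(seed, m, d, 10 + tr),
                                   correct_port = correct)
        traj$mouse <- m; traj$day <- d; traj$trial <- tr
        trials[[length(trials) + 1]] <- traj
        v <- attr(traj, "visits")
        if (!is.null(v) && nrow(v)) {
          visit_tab <- rbind(visit_tab,
                             cbind(mouse = m, day = d, trial = tr, v))
        }
      }
    }
  }
  list(rests = rests, trials = trials,
       ground_truth = list(coupling = config$coupling,
                           nrem_activity = amp_tab, drive = drive_tab,
                           visits = visit_tab))
}
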