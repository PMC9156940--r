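# Maze and object-arena behavioral statistics from tracking tables.

#' Instantaneous nose speed
#'
#' Central finite differences of the nose position times the frame rate, with
#' one-sided differences at the endpoints and optional boxcar smoothing.
#'
#' @param traj a [trajectory()].
#' @param smoothing boxcar width in frames (default 3; 1 disables).
#' @param point which tracked point to differentiate (`"nose"` or
#'   `"center"`).
#' @return numeric speed series, cm/s, one value per frame.
#' @export
nose_speed <- function(traj, smoothing = 3, point = "nose") {
  p <- traj[[point]]
  n <- nrow(p)
  nl_assert(n >= 2, "need at least 2 samples")
  vx <- numeric(n); vy <- numeric(n)
  vx[2:(n - 1)] <- (p[3:n, 1] - p[1:(n - 2), 1]) / 2
  vy[2:(n - 1)] <- (p[3:n, 2] - p[1:(n - 2), 2]) / 2
  vx[1] <- p[2, 1] - p[1, 1]; vy[1] <- p[2, 2] - p[1, 2]
  vx[n] <- p[n, 1] - p[n - 1, 1]; vy[n] <- p[n, 2] - p[n - 1, 2]
  sp <- sqrt(vx^2 + vy^2) * traj$fs
  boxcar(sp, smoothing)
}

# per-frame port index (0 = outside every zone) from the zone predicate:
# zone_r[1] <= |nose| <= zone_r[2] and angular deviation <= zone_half_angle
frame_port <- function(traj, geom) {
  r <- sqrt(rowSums(traj$nose^2))
  ang <- atan2(traj$nose[, 2], traj$nose[, 1]) * 180 / pi
  port <- integer(nrow(traj$nose))
  in_ring <- r >= geom$zone_r[1] & r <= geom$zone_r[2]
  for (k in seq_len(geom$n_ports)) {
    hit <- in_ring & ang_diff(ang, geom$port_angles[k]) <= geom$zone_half_angle
    port[hit] <- k
  }
  port
}

#' Detect port-zone visits
#'
#' A visit opens at the first frame the nose satisfies the port-zone
#' predicate (annulus between the zone radii, within the zone half-angle of a
#' port bearing); re-entries into the *same* port within `merge_gap` seconds
#' of the exit merge into one visit.  Each visit's speed is the mean nose
#' speed from -0.5 s to +2.5 s around entry ([port_visit_speed()]); visits
#' whose window overruns the trajectory are flagged `unassigned` and excluded
#' from mixture fitting.
#'
#' @param traj a [trajectory()].
#' @param geom a [maze_geometry()].
#' @param merge_gap re-entry merge gap, seconds (default 0.5).
#' @return data.frame `port`, `entry_time`, `exit_time`, `visit_speed`,
#'   `motif` (initially `"unassigned"` for truncated windows, `NA` otherwise
#'   until mixture assignment).
#' @export
detect_port_entries <- function(traj, geom, merge_gap = 0.5) {
  port <- frame_port(traj, geom)
  r <- rle(port)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  vis <- data.frame(port = r$values, start = starts, end = ends)
  vis <- vis[vis$port != 0, , drop = FALSE]
  if (!nrow(vis)) {
    return(data.frame(port = integer(0), entry_time = numeric(0),
                      exit_time = numeric(0), visit_speed = numeric(0),
                      motif = character(0)))
  }
  # merge re-entries to the same port across short gaps
  merged <- vis[1, , drop = FALSE]
  if (nrow(vis) > 1) {
    for (j in 2:nrow(vis)) {
      last <- nrow(merged)
      gap <- (vis$start[j] - merged$end[last] - 1) / traj$fs
      if (vis$port[j] == merged$port[last] && gap <= merge_gap) {
        merged$end[last] <- vis$end[j]
      } else {
        merged <- rbind(merged, vis[j, , drop = FALSE])
      }
    }
  }
  vis <- merged
  out <- data.frame(port = vis$port,
                    entry_time = traj$time[vis$start],
                    exit_time = traj$time[vis$end])
  sp <- nose_speed(traj)
  out$visit_speed <- vapply(out$entry_time, function(et)
    port_visit_speed(traj, et, speed = sp), numeric(1))
  out$motif <- ifelse(is.na(out$visit_speed), "unassigned", NA_character_)
  out
}

#' Mean nose speed in the port-visit window
#'
#' Arithmetic mean of the absolute nose speed from `window[1]` to
#' `window[2]` seconds around port entry (defaults -0.5 s to +2.5 s,
#' endpoints included).  Returns `NA` when the window is not fully contained
#' in the trajectory.
#'
#' @param traj a [trajectory()].
#' @param entry_time visit entry time, seconds.
#' @param window `c(pre, post)` seconds relative to entry.
#' @param speed optional precomputed [nose_speed()] series.
#' @return speed in cm/s, or `NA` for a truncated window.
#' @export
port_visit_speed <- function(traj, entry_time, window = c(-0.5, 2.5),
                             speed = NULL) {
  if (is.null(speed)) speed <- nose_speed(traj)
  lo <- entry_time + window[1]; hi <- entry_time + window[2]
  eps <- 1e-9
  if (lo < traj$time[1] - eps || hi > traj$time[length(traj$time)] + eps) {
    return(NA_real_)
  }
  sel <- traj$time >= lo - eps & traj$time <= hi + eps
  mean(speed[sel])
}

# 1-D Gaussian mixture by EM, deterministic quantile-based initialization
gmm_em_1d <- function(x, k, max_iter = 200, tol = 1e-8) {
  n <- length(x)
  mu <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  sd0 <- stats::sd(x) / k
  sig <- rep(max(sd0, 1e-3), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sig[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    ll <- sum(log(rs))
    resp <- dens / rs
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    for (j in seq_len(k)) {
      sig[j] <- sqrt(max(sum(resp[, j] * (x - mu[j])^2) / nk[j], 1e-6))
    }
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  o <- order(mu)
  list(k = k, means = mu[o], sds = sig[o], weights = w[o], loglik = ll,
       responsibilities = resp[, o, drop = FALSE])
}

#' Fit a Gaussian mixture to port-visit speeds
#'
#' Expectation-maximization fits of `k`-component Gaussian mixtures for each
#' candidate `k`; the Bayesian information criterion selects the model.  When
#' the selected model has two components, visits are assigned slow/fast by
#' the posterior under that model and the slow/fast decision boundary (equal
#' posterior point between the two means) is reported.
#'
#' @param speeds port-visit speeds, cm/s (>= 20 values).
#' @param k_candidates candidate component counts, default `1:3`.
#' @return list of class `speed_mixture`: `selected_k`, `means`, `sds`,
#'   `weights`, `bic` (named per k), `assignment` ("slow"/"fast", only for
#'   k = 2), `boundary`.
#' @export
fit_speed_mixture <- function(speeds, k_candidates = 1:3) {
  speeds <- speeds[is.finite(speeds)]
  if (length(speeds) < 20) nl_stop("need at least 20 visit speeds",
                                   "insufficient_data")
  if (stats::sd(speeds) < 1e-12) nl_stop("speeds have no variance",
                                         "insufficient_variance")
  fits <- lapply(k_candidates, function(k) gmm_em_1d(speeds, k))
  bic <- vapply(fits, function(f)
    -2 * f$loglik + (3 * f$k - 1) * log(length(speeds)), numeric(1))
  names(bic) <- paste0("k", k_candidates)
  best <- fits[[which.min(bic)]]
  assignment <- NULL; boundary <- NA_real_
  if (best$k == 2) {
    assignment <- ifelse(best$responsibilities[, 1] >=
                           best$responsibilities[, 2], "slow", "fast")
    grid <- seq(best$means[1], best$means[2], length.out = 2000)
    post1 <- best$weights[1] * stats::dnorm(grid, best$means[1], best$sds[1])
    post2 <- best$weights[2] * stats::dnorm(grid, best$means[2], best$sds[2])
    boundary <- grid[which.min(abs(post1 - post2))]
  }
  structure(list(selected_k = best$k, means = best$means, sds = best$sds,
                 weights = best$weights, bic = bic, assignment = assignment,
                 boundary = boundary, n = length(speeds)),
            class = "speed_mixture")
}

#' @export
print.speed_mixture <- function(x, ...) {
  cat(sprintf("<speed_mixture> k=%d (n=%d)\n", x$selected_k, x$n))
  cat(sprintf("  means: %s | weights: %s\n",
              paste(signif(x$means, 3), collapse = ", "),
              paste(signif(x$weights, 3), collapse = ", ")))
  invisible(x)
}

# nose heading over a 3-frame displacement, unit vectors; NA rows where still
nose_heading <- function(traj) {
  p <- traj$nose
  n <- nrow(p)
  dx <- c(p[4:n, 1], rep(NA, 3)) - p[, 1]
  dy <- c(p[4:n, 2], rep(NA, 3)) - p[, 2]
  nrm <- sqrt(dx^2 + dy^2)
  cbind(dx / nrm, dy / nrm)
}

#' Count correct-pod visits with and without entry
#'
#' An approach begins when the nose enters the `pod_perimeter` (3 cm) zone
#' around the correct pod.  It ends in *entry* when the nose crosses the pod
#' door line (radially beyond `zone_r[2]` within the port wedge); it ends in
#' a *visit without entry* when the nose exits the perimeter, or when the
#' nose heading (3-frame displacement) deviates more than 90 degrees from
#' the nose-to-pod bearing for at least 2 consecutive frames inside the
#' perimeter (the "turned away" rule).
#'
#' @param traj a [trajectory()].
#' @param geom a [maze_geometry()] with `correct_port` set.
#' @return list `with_entry`, `without_entry` (counts).
#' @export
correct_pod_visits <- function(traj, geom) {
  pod <- pod_center(geom)
  nose <- traj$nose
  d <- sqrt((nose[, 1] - pod[1])^2 + (nose[, 2] - pod[2])^2)
  inside <- d <= geom$pod_perimeter
  r <- sqrt(rowSums(nose^2))
  ang <- atan2(nose[, 2], nose[, 1]) * 180 / pi
  door <- r > geom$zone_r[2] &
    ang_diff(ang, geom$port_angles[geom$correct_port]) <= geom$zone_half_angle
  hd <- nose_heading(traj)
  to_pod_x <- pod[1] - nose[, 1]; to_pod_y <- pod[2] - nose[, 2]
  tp_n <- sqrt(to_pod_x^2 + to_pod_y^2); tp_n[tp_n == 0] <- 1
  away <- (hd[, 1] * to_pod_x + hd[, 2] * to_pod_y) / tp_n < 0
  away[is.na(away)] <- FALSE

  with_entry <- 0L; without_entry <- 0L
  n <- length(d); i <- 1L
  while (i <= n) {
    if (!inside[i]) { i <- i + 1L; next }
    entered <- FALSE; turned <- FALSE; away_run <- 0L
    j <- i
    while (j <= n && inside[j]) {
      if (door[j] && d[j] <= geom$pod_perimeter) entered <- TRUE
      away_run <- if (away[j]) away_run + 1L else 0L
      if (away_run >= 2L) turned <- TRUE
      if (entered) break
      j <- j + 1L
    }
    if (entered) with_entry <- with_entry + 1L
    else without_entry <- without_entry + 1L  # exited perimeter or turned away
    # skip to the end of this approach episode
    while (j <= n && inside[j]) j <- j + 1L
    i <- j
  }
  list(with_entry = with_entry, without_entry = without_entry)
}

# frame index of the first pod entry (door-line crossing inside the
# perimeter), or NA for a timeout trial
first_entry_frame <- function(traj, geom) {
  pod <- pod_center(geom)
  nose <- traj$nose
  d <- sqrt((nose[, 1] - pod[1])^2 + (nose[, 2] - pod[2])^2)
  r <- sqrt(rowSums(nose^2))
  ang <- atan2(nose[, 2], nose[, 1]) * 180 / pi
  hit <- which(d <= geom$pod_perimeter & r > geom$zone_r[2] &
                 ang_diff(ang, geom$port_angles[geom$correct_port]) <=
                   geom$zone_half_angle)
  if (length(hit)) hit[1] else NA_integer_
}

#' Per-trial distance and velocity metrics
#'
#' Cumulative center-point path length until correct-pod entry (or the whole
#' trial for timeouts), optionally normalized by a reference trial's
#' distance; mean center speed; and the ratio of mean speed to a first
#' trial's mean speed.
#'
#' @param traj a [trajectory()].
#' @param geom a [maze_geometry()].
#' @param reference_trial trajectory whose escape distance normalizes this
#'   trial's (typically the final pre-sleep trial), or `NULL`.
#' @param first_trial trajectory whose mean velocity anchors
#'   `velocity_ratio`, or `NULL`.
#' @return list `distance_to_escape`, `normalized_distance`,
#'   `mean_velocity`, `velocity_ratio`, `escaped` (logical).
#' @export
trial_metrics <- function(traj, geom, reference_trial = NULL,
                          first_trial = NULL) {
  metrics_core <- function(tr) {
    ef <- first_entry_frame(tr, geom)
    last <- if (is.na(ef)) n_frames(tr) else ef
    p <- tr$center[seq_len(last), , drop = FALSE]
    dist <- sum(sqrt(rowSums(diff(p)^2)))
    spd <- nose_speed(tr, point = "center")
    list(distance = dist, mean_velocity = mean(spd[seq_len(last)]),
         escaped = !is.na(ef))
  }
  me <- metrics_core(traj)
  normalized <- NA_real_
  if (!is.null(reference_trial)) {
    ref <- metrics_core(reference_trial)
    if (ref$distance <= 0) nl_stop("reference trial has zero distance",
                                   "invalid_reference")
    normalized <- me$distance / ref$distance
  }
  vratio <- NA_real_
  if (!is.null(first_trial)) {
    f <- metrics_core(first_trial)
    if (f$mean_velocity <= 0) nl_stop("first trial has zero mean velocity",
                                      "invalid_reference")
    vratio <- me$mean_velocity / f$mean_velocity
  }
  list(distance_to_escape = me$distance, normalized_distance = normalized,
       mean_velocity = me$mean_velocity, velocity_ratio = vratio,
       escaped = me$escaped)
}

#' Novelty preference ratio
#'
#' Fraction of object-exploration time spent at the novel object:
#' `time_novel / (time_novel + time_familiar)`, where exploration means the
#' nose is within `perimeter` cm of an object center.  0.5 is the
#' no-preference chance level.
#'
#' @param traj a [trajectory()].
#' @param object_centers 2 x 2 matrix of object centers, row 1 = novel; if
#'   omitted, taken from `attr(traj, "objects")`.
#' @param perimeter exploration perimeter, cm (default 2).
#' @return ratio in `[0, 1]`.
#' @export
novelty_preference <- function(traj, object_centers = NULL, perimeter = 2) {
  if (is.null(object_centers)) object_centers <- attr(traj, "objects")
  nl_assert(!is.null(object_centers) && nrow(object_centers) == 2,
            "object_centers must be a 2 x 2 matrix (row 1 = novel)")
  n <- n_frames(traj)
  d1 <- sqrt((traj$nose[, 1] - object_centers[1, 1])^2 +
               (traj$nose[, 2] - object_centers[1, 2])^2)
  d2 <- sqrt((traj$nose[, 1] - object_centers[2, 1])^2 +
               (traj$nose[, 2] - object_centers[2, 2])^2)
  t_nov <- sum(d1 <= perimeter) / traj$fs
  t_fam <- sum(d2 <= perimeter) / traj$fs
  if (t_nov + t_fam == 0) nl_stop("no object exploration time",
                                  "undefined_ratio")
  t_nov / (t_nov + t_fam)
}

#' Spatial occupancy map
#'
#' Dwell time (seconds) of the body center in square spatial bins covering
#' the arena; totals the trial duration exactly.
#'
#' @param traj a [trajectory()].
#' @param geom a [maze_geometry()].
#' @param bin bin side, cm.
#' @return matrix of dwell seconds with bin-center coordinates in
#'   `dimnames`.
#' @export
occupancy_map <- function(traj, geom, bin = 5) {
  nl_assert(bin > 0, "bin must be > 0")
  r <- arena_radius(geom)
  breaks <- seq(-r - bin, r + bin, by = bin)
  ix <- findInterval(traj$center[, 1], breaks, rightmost.closed = TRUE)
  iy <- findInterval(traj$center[, 2], breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1
  m <- matrix(0, nb, nb)
  for (i in seq_along(ix)) m[ix[i], iy[i]] <- m[ix[i], iy[i]] + 1
  m <- m / traj$fs
  centers <- breaks[-length(breaks)] + bin / 2
  dimnames(m) <- list(x = signif(centers, 6), y = signif(centers, 6))
  m
}
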