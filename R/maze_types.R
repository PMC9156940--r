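#' Barnes-style maze geometry
#'
#' Circular arena with escape ports arranged around the edge.  Port zones are
#' annular wedges (between `zone_r[1]` and `zone_r[2]` cm from the maze
#' center, within `zone_half_angle` degrees of a port's bearing); a nose
#' crossing into a zone defines a port visit.  The correct (open) pod sits
#' just outside the arena edge at its port's bearing; a 3 cm perimeter around
#' it defines correct-pod approaches.
#'
#' @param arena_diameter arena diameter, cm.
#' @param n_ports number of ports; default 8 evenly spaced.
#' @param port_angles port bearings in degrees (counter-clockwise from +x);
#'   default evenly spaced.
#' @param zone_r `c(inner, outer)` port-zone radii, cm.
#' @param zone_half_angle angular half-width of a port zone, degrees.
#' @param correct_port index (1-based) of the open port.
#' @param pod_perimeter radius of the correct-pod approach perimeter, cm.
#' @param pod_offset how far beyond the arena edge the pod center sits, cm;
#'   0 places the pod door at the wall so part of its 3 cm perimeter is
#'   reachable from inside the arena without crossing the door line.
#' @param object_perimeter radius of the object-exploration zone, cm.
#' @return object of class `maze_geometry`.
#' @export
maze_geometry <- function(arena_diameter = 120,
                          n_ports = 8L,
                          port_angles = NULL,
                          zone_r = c(50, 58),
                          zone_half_angle = 6,
                          correct_port = 1L,
                          pod_perimeter = 3,
                          pod_offset = 0,
                          object_perimeter = 2) {
  if (is.null(port_angles)) {
    port_angles <- seq(0, 360, length.out = n_ports + 1L)[seq_len(n_ports)]
  }
  nl_assert(length(port_angles) == n_ports, "port_angles length must equal n_ports")
  nl_assert(anyDuplicated(port_angles %% 360) == 0, "port_angles must be distinct")
  nl_assert(zone_r[1] < zone_r[2], "zone_r inner must be < outer")
  nl_assert(zone_r[2] <= arena_diameter / 2,
            "zone_r outer must be <= arena radius")
  nl_assert(correct_port >= 1 && correct_port <= n_ports,
            "correct_port out of range")
  structure(list(arena_diameter = arena_diameter, n_ports = as.integer(n_ports),
                 port_angles = port_angles, zone_r = zone_r,
                 zone_half_angle = zone_half_angle,
                 correct_port = as.integer(correct_port),
                 pod_perimeter = pod_perimeter, pod_offset = pod_offset,
                 object_perimeter = object_perimeter),
            class = "maze_geometry")
}

arena_radius <- function(geom) geom$arena_diameter / 2

pod_center <- function(geom, port = geom$correct_port) {
  r <- arena_radius(geom) + geom$pod_offset
  a <- geom$port_angles[port] * pi / 180
  c(r * cos(a), r * sin(a))
}

# smallest absolute angular difference in degrees
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Maze tracking trajectory
#'
#' 10 Hz (by default) nose/center/tail coordinates in cm with the maze center
#' at the origin, plus body area, with trial provenance attributes.
#'
#' @param time sample times, seconds (uniform).
#' @param nose,center,tail n x 2 matrices of x,y coordinates (cm).
#' @param area body area per frame (cm^2).
#' @param fs sampling rate, Hz.
#' @param mouse,day,trial provenance identifiers.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(time, nose, center, tail, area, fs = 10,
                       mouse = NA, day = NA, trial = NA) {
  n <- length(time)
  nose <- as.matrix(nose); center <- as.matrix(center); tail <- as.matrix(tail)
  nl_assert(nrow(nose) == n && nrow(center) == n && nrow(tail) == n &&
              length(area) == n, "all components must share length")
  nl_assert(n < 2 || all(diff(time) > 0), "time must be strictly increasing")
  structure(list(time = time, nose = nose, center = center, tail = tail,
                 area = as.numeric(area), fs = fs,
                 mouse = mouse, day = day, trial = trial),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames @ %g Hz (%.1f s) mouse=%s day=%s trial=%s\n",
              length(x$time), x$fs, length(x$time) / x$fs,
              x$mouse, x$day, x$trial))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_s = x$time,
             nose_x = x$nose[, 1], nose_y = x$nose[, 2],
             center_x = x$center[, 1], center_y = x$center[, 2],
             tail_x = x$tail[, 1], tail_y = x$tail[, 2],
             area = x$area)
}

n_frames <- function(traj) length(traj$time)
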