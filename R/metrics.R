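#' Phase lag of the bead behind a rotating field
#'
#' Difference between the (unwrapped) field angle and the bead's azimuth
#' about `centre`, in degrees.  A bead tracking the rotating potential
#' minimum synchronously has a small constant lag; a growing lag signals
#' the overcritical regime that precedes looping.
#'
#' @param trajectory a `bead_trajectory` (see [simulate_bead()]).
#' @param field a rotating-mode [field_sequence()].
#' @param centre in-plane rotation centre, 2-vector (m).
#' @return data frame with columns `t` and `lag_deg`.
#' @export
phase_lag <- function(trajectory, field, centre = c(0, 0)) {
  if (field$mode != "rotating")
    stop("phase_lag() needs a rotating-mode field")
  az <- atan2(trajectory$y_unwrapped - centre[2],
              trajectory$x_unwrapped - centre[1]) * 180 / pi
  az <- unwrap_deg(az)
  lag <- field_angle(field, trajectory$t) - az
  data.frame(t = trajectory$t, lag_deg = lag)
}

# unwrap a degree series (remove 360-degree jumps)
unwrap_deg <- function(a) {
  d <- diff(a)
  d <- d - 360 * round(d / 360)
  c(a[1], a[1] + cumsum(d))
}

#' Detect looping events
#'
#' A looping event is a maximal interval during which the bead's radial
#' distance from `centre` exceeds `structure_radius + r_mb + threshold` and
#' then returns below it: the bead detaches from the edge minimum, loops
#' outward (and typically upward), and is recaptured.
#'
#' @param trajectory a `bead_trajectory`.
#' @param centre in-plane structure centre, 2-vector (m).
#' @param structure_radius radius of the parent structure (m).
#' @param r_mb bead radius (m).
#' @param threshold radial detachment margin (m); default `0.5 * r_mb`.
#' @return data frame, one row per completed event: `t_start, t_end,
#'   duration, max_radius, max_edge_distance, max_z` (metres/seconds).
#' @export
detect_looping <- function(trajectory, centre, structure_radius, r_mb,
                           threshold = 0.5 * r_mb) {
  rr <- sqrt((trajectory$x_unwrapped - centre[1])^2 +
             (trajectory$y_unwrapped - centre[2])^2)
  lim <- structure_radius + r_mb + threshold
  above <- rr > lim
  ev <- run_intervals(above)
  # only events that end within the trajectory (the bead returned)
  ev <- ev[ev$end < length(above), , drop = FALSE]
  if (nrow(ev) == 0)
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), max_radius = numeric(0),
                      max_edge_distance = numeric(0), max_z = numeric(0)))
  res <- lapply(seq_len(nrow(ev)), function(q) {
    ii <- ev$start[q]:ev$end[q]
    data.frame(t_start = trajectory$t[ev$start[q]],
               t_end = trajectory$t[ev$end[q]],
               duration = trajectory$t[ev$end[q]] - trajectory$t[ev$start[q]],
               max_radius = max(rr[ii]),
               max_edge_distance = max(rr[ii]) - structure_radius,
               max_z = max(trajectory$z[ii]))
  })
  do.call(rbind, res)
}

# maximal runs of TRUE as start/end indices
run_intervals <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Detect rest intervals
#'
#' Maximal intervals during which the bead speed stays strictly below
#' `speed_floor` for at least `min_duration` seconds, e.g. the stationary
#' wait of a bead parked between two track elements while the field sweeps.
#'
#' @param trajectory a `bead_trajectory`.
#' @param speed_floor speed threshold (m/s); default 1 micrometre/s.
#' @param min_duration minimum interval length (s).
#' @return data frame with `t_start, t_end, duration` (s).
#' @export
detect_rests <- function(trajectory, speed_floor = 1e-6, min_duration = 0) {
  speed <- sqrt(trajectory$vx^2 + trajectory$vy^2 + trajectory$vz^2)
  slow <- speed < speed_floor
  ev <- run_intervals(slow)
  if (nrow(ev) == 0)
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0)))
  out <- data.frame(t_start = trajectory$t[ev$start],
                    t_end = trajectory$t[ev$end])
  out$duration <- out$t_end - out$t_start
  out[out$duration >= min_duration, , drop = FALSE]
}

#' Net displacement per field period
#'
#' @param trajectory a `bead_trajectory`.
#' @param period field period (s).
#' @return data frame with one row per whole period: `period_index, dx, dy`
#'   (m, unwrapped).
#' @export
displacement_per_period <- function(trajectory, period) {
  tmax <- max(trajectory$t)
  np <- floor(tmax / period + 1e-9)
  if (np < 1)
    return(data.frame(period_index = integer(0), dx = numeric(0),
                      dy = numeric(0)))
  at <- function(tq, col) {
    stats::approx(trajectory$t, trajectory[[col]], xout = tq, rule = 2)$y
  }
  tq0 <- (seq_len(np) - 1) * period
  tq1 <- seq_len(np) * period
  data.frame(period_index = seq_len(np),
             dx = at(tq1, "x_unwrapped") - at(tq0, "x_unwrapped"),
             dy = at(tq1, "y_unwrapped") - at(tq0, "y_unwrapped"))
}
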