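# Physical environment of the reaching task: viscous curl force-field,
# reference minimum-jerk kinematics, and ideal compensatory forces.
#
# Conventions: positions in metres, velocities in m/s, forces in N,
# directions in degrees CCW from +x. A clockwise (CW) field has positive
# viscosity and deflects a reach toward smaller movement angles; the
# counter-clockwise (CCW) field has negative viscosity.

#' Viscous curl force-field
#'
#' Force exerted by a velocity-dependent curl field,
#' `F = B * (v_y, -v_x)`, where `B` is the signed field viscosity in
#' N/(m/s). The force is always orthogonal to the velocity, so the field
#' performs no mechanical work on the hand.
#'
#' @param velocity Hand velocity in m/s: a length-2 vector `c(vx, vy)` or an
#'   n x 2 matrix (one row per sample).
#' @param viscosity Signed field viscosity `B` in N/(m/s). Positive values
#'   give a clockwise field.
#' @return Force in N with the same shape as `velocity`.
#' @examples
#' curl_force(c(0, -0.3), 9)     # (-2.7, 0) N
#' @export
curl_force <- function(velocity, viscosity) {
  if (!is.numeric(velocity) || !all(is.finite(velocity))) {
    stop("`velocity` must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(viscosity) || length(viscosity) != 1L || !is.finite(viscosity)) {
    stop("`viscosity` must be a single finite number", call. = FALSE)
  }
  if (is.matrix(velocity)) {
    if (ncol(velocity) != 2L) stop("`velocity` matrix must have 2 columns", call. = FALSE)
    cbind(viscosity * velocity[, 2L], -viscosity * velocity[, 1L],
          deparse.level = 0)
  } else {
    if (length(velocity) != 2L) stop("`velocity` must have length 2", call. = FALSE)
    c(viscosity * velocity[2L], -viscosity * velocity[1L])
  }
}

#' Minimum-jerk reference trajectory
#'
#' Straight point-to-point reach with a fifth-order minimum-jerk speed
#' profile: `s(tau) = d (10 tau^3 - 15 tau^4 + 6 tau^5)`. Velocity is zero at
#' both endpoints and the peak speed is `1.875 * distance / duration`,
#' reached at mid-movement. The default duration (0.621 s) makes a 10-cm
#' reach peak at 0.302 m/s, the mean peak speed of the task the simulator
#' emulates.
#'
#' @param direction Movement direction in degrees CCW from +x.
#' @param distance Reach distance in metres.
#' @param duration Movement duration in seconds.
#' @param dt Sample interval in seconds (default 0.005, i.e. 200 Hz).
#' @param origin Length-2 start position in metres.
#' @return A tibble of class `reach_trajectory` with columns `t`, `x`, `y`
#'   (m), `vx`, `vy` (m/s), and attributes `direction`, `distance`,
#'   `duration`, `dt`.
#' @examples
#' traj <- min_jerk_trajectory(90)
#' max(sqrt(traj$vx^2 + traj$vy^2))   # ~0.302 m/s
#' @export
min_jerk_trajectory <- function(direction = 90, distance = 0.1,
                                duration = 0.621, dt = 0.005,
                                origin = c(0, 0)) {
  if (!is.numeric(distance) || distance <= 0) {
    stop("`distance` must be positive", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  if (!is.numeric(dt) || dt <= 0 || dt > duration) {
    stop("`dt` must be positive and no longer than `duration`", call. = FALSE)
  }
  t <- seq(0, duration, by = dt)
  if (t[length(t)] < duration) t <- c(t, duration)
  tau <- t / duration
  s <- distance * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  sd1 <- distance / duration * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  u <- c(cos(direction * pi / 180), sin(direction * pi / 180))
  out <- tibble::tibble(
    t = t,
    x = origin[1L] + s * u[1L],
    y = origin[2L] + s * u[2L],
    vx = sd1 * u[1L],
    vy = sd1 * u[2L]
  )
  structure(out,
            class = c("reach_trajectory", class(out)),
            direction = wrap_angle(direction),
            distance = distance, duration = duration, dt = dt)
}

#' Peak hand speed of a trajectory
#'
#' @param traj A trajectory with `vx`, `vy` columns.
#' @return Peak speed in m/s.
#' @export
peak_speed <- function(traj) {
  max(sqrt(traj$vx^2 + traj$vy^2))
}

#' Ideal field-compensating force along a trajectory
#'
#' The force a fully adapted subject would produce to null the curl field at
#' every sample: the pointwise negative of [curl_force()] evaluated on the
#' trajectory's velocities. For a straight minimum-jerk reach the lateral
#' profile is bell-shaped, mirroring the speed profile.
#'
#' @param traj A [min_jerk_trajectory()] (or any tibble with `t`, `vx`, `vy`).
#' @param viscosity Signed field viscosity in N/(m/s).
#' @return Tibble with columns `t`, `fx`, `fy` (N).
#' @export
ideal_compensation_force <- function(traj, viscosity) {
  f <- curl_force(cbind(traj$vx, traj$vy), viscosity)
  tibble::tibble(t = traj$t, fx = -f[, 1L], fy = -f[, 2L])
}

#' Write / read a trajectory as CSV
#'
#' Serializes the uniform time series with columns `t, x, y, vx, vy` in SI
#' units.
#'
#' @param traj Trajectory tibble.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a trajectory tibble.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(tibble::as_tibble(traj)[, c("t", "x", "y", "vx", "vy")], path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
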