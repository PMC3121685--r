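# Trial-by-trial state-space learning rules over movement direction with a
# local Gaussian motor primitive.
#
# The adaptation state x(theta) holds the compensated viscosity, in
# N/(m/s), as a function of movement direction theta on a dense wrap-aware
# grid. Sign convention (used consistently throughout the package): positive
# state is compensation appropriate for the CCW field (negative viscosity),
# so a subject fully adapted to a field of signed viscosity B has
# x(theta_trained) = -B. This is the axis on which generalization patterns
# are conventionally plotted (CCW-appropriate adaptation positive).
#
# Per trial n with directional error e_n (deg) the state updates as
#   x_{n+1}(theta) = A * x_n(theta) + e_n * k * g(theta - theta_ref, sigma)
# where A is the retention coefficient, k the learning gain, g a Gaussian
# primitive, and theta_ref the planned direction under plan-referenced
# learning (PRL) or the actual direction under motion-referenced learning
# (MRL). Null-field and error-clamp trials apply pure retention decay.

#' Directional primitive width from a velocity-space width
#'
#' Converts the width of a Gaussian motor primitive given in velocity space
#' (m/s) into an equivalent width over movement direction (degrees). The
#' activation of a primitive centred on the velocity path of one straight
#' minimum-jerk reach is evaluated along the path of a reach rotated by
#' `dtheta` (the two paths share the speed profile `s(t)`, so the
#' instantaneous separation is `2 s(t) sin(dtheta/2)`), averaged over the
#' movement with `s(t)^2` weights -- the portion of the movement where
#' velocity-dependent forces act -- and the resulting direction-tuning
#' curve is least-squares fitted with a Gaussian. With the defaults
#' (`sigma_v` = 0.12 m/s, 10-cm reach peaking at 0.302 m/s) the conversion
#' gives about 28.9 degrees. Note this is substantially wider than the
#' chord subtended at peak speed alone (`sigma_v / v_peak` ~ 22.8 deg),
#' because much of the reach is spent below peak speed where a given
#' angular offset maps to a small velocity offset.
#'
#' @param sigma_v Primitive width in velocity space, m/s.
#' @param distance,duration Reference reach (defaults 0.1 m, 0.621 s).
#' @param dt Integration step, s.
#' @return Equivalent direction-space width, degrees.
#' @export
primitive_sigma_from_velocity <- function(sigma_v = 0.12, distance = 0.1,
                                          duration = 0.621, dt = 0.001) {
  stopifnot(sigma_v > 0, distance > 0, duration > 0)
  tau <- seq(0, 1, by = dt / duration)
  s <- distance / duration * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  th <- seq(0, 180, by = 0.5)
  a <- th * pi / 180
  w <- s^2 / sum(s^2)
  tune <- vapply(a, function(aa) {
    sum(w * exp(-2 * (s * sin(aa / 2))^2 / sigma_v^2))
  }, numeric(1))
  stats::optimize(function(sg) sum((tune - exp(-th^2 / (2 * sg^2)))^2),
                  interval = c(1, 120))$minimum
}

#' Learning-rule parameters
#'
#' @param retention Per-trial multiplicative retention `A` of the adaptation
#'   state, in (0, 1]. Default 0.98.
#' @param gain Learning gain `k` in N/(m/s) of compensation per degree of
#'   directional error. The default (0.45/12.6 ~ 0.0357) makes a single
#'   naive trial in the 9 N/(m/s) field produce ~5% of full compensation at
#'   the primitive centre.
#' @param primitive_sigma Width of the Gaussian motor primitive in degrees
#'   of movement direction. Default ~28.9 deg: the direction-space
#'   equivalent of a 0.12 m/s velocity-space primitive, derived by
#'   [primitive_sigma_from_velocity()].
#' @param hypothesis `"MRL"` (update centred on the actual movement
#'   direction) or `"PRL"` (centred on the planned direction).
#' @param cw_gain_scale Optional multiplier (>= 0) applied to `gain` on
#'   CW-field trials, emulating a learning-rate asymmetry between field
#'   directions. Default 1 (off).
#' @return A list of class `learning_params`.
#' @export
learning_params <- function(retention = 0.98,
                            gain = 0.45 / 12.6,
                            primitive_sigma = primitive_sigma_from_velocity(),
                            hypothesis = c("MRL", "PRL"),
                            cw_gain_scale = 1) {
  hypothesis <- match.arg(hypothesis)
  if (!is.numeric(retention) || retention <= 0 || retention > 1) {
    stop("`retention` must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(gain) || gain < 0) stop("`gain` must be >= 0", call. = FALSE)
  if (!is.numeric(primitive_sigma) || primitive_sigma <= 0) {
    stop("`primitive_sigma` must be > 0", call. = FALSE)
  }
  if (!is.numeric(cw_gain_scale) || cw_gain_scale < 0) {
    stop("`cw_gain_scale` must be >= 0", call. = FALSE)
  }
  structure(list(retention = retention, gain = gain,
                 primitive_sigma = primitive_sigma,
                 hypothesis = hypothesis,
                 cw_gain_scale = cw_gain_scale),
            class = "learning_params")
}

#' Naive adaptation state on a dense direction grid
#'
#' @param grid_step Grid spacing in degrees (default 1). The grid covers
#'   `[-180, 180)`.
#' @return A tibble of class `adaptation_state` with columns `direction`
#'   (degrees) and `value` (compensated viscosity, N/(m/s); positive =
#'   compensation appropriate for the CCW field). A naive state is
#'   identically zero.
#' @export
adaptation_state <- function(grid_step = 1) {
  stopifnot(is.numeric(grid_step), grid_step > 0, 360 %% grid_step == 0)
  out <- tibble::tibble(direction = seq(-180, 180 - grid_step, by = grid_step),
                        value = 0)
  structure(out, class = c("adaptation_state", class(out)))
}

as_adaptation_state <- function(direction, value) {
  out <- tibble::tibble(direction = direction, value = value)
  structure(out, class = c("adaptation_state", class(out)))
}

#' Gaussian motor-primitive activation
#'
#' `exp(-d^2 / (2 sigma^2))` with `d` the wrap-aware angular offset from the
#' primitive centre. Symmetric, maximal (1) at zero offset.
#'
#' @param delta Angular offset(s) from the primitive centre, degrees.
#' @param sigma Primitive width in degrees (> 0).
#' @return Activation weight(s) in `[0, 1]`.
#' @examples
#' primitive_activation(0, 22.8)          # 1
#' primitive_activation(22.8, 22.8)       # exp(-1/2)
#' @export
primitive_activation <- function(delta, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  d <- wrap_angle(delta)
  exp(-d^2 / (2 * sigma^2))
}

#' Read the adaptation state at arbitrary directions
#'
#' Wrap-aware linear interpolation of the state grid.
#'
#' @param state An [adaptation_state()].
#' @param directions Directions in degrees.
#' @return Compensated viscosity at each direction, N/(m/s).
#' @export
state_at <- function(state, directions) {
  grid <- state$direction
  step <- grid[2L] - grid[1L]
  d <- wrap_angle(directions)
  d[d == 180] <- -180  # grid covers [-180, 180)
  i0 <- floor((d - grid[1L]) / step)
  frac <- (d - grid[1L]) / step - i0
  n <- length(grid)
  i1 <- (i0 + 1L) %% n
  state$value[i0 + 1L] * (1 - frac) + state$value[i1 + 1L] * frac
}

#' One trial-by-trial state update
#'
#' Applies the learning rule for a single trial. On force-field trials
#' (`field_sign` +1 for CW, -1 for CCW) the state gains an error-scaled
#' Gaussian increment centred on the planned direction (PRL) or the actual
#' direction (MRL); on null-field and error-clamp trials (`field_sign = 0`)
#' the error carries no field information and the state undergoes pure
#' retention decay.
#'
#' @param state An [adaptation_state()].
#' @param planned_direction,actual_direction Degrees.
#' @param error Directional error for the trial,
#'   `wrap_angle(actual - planned)`, degrees.
#' @param field_sign +1 (CW field), -1 (CCW field) or 0 (null / error-clamp).
#' @param params A [learning_params()].
#' @return The updated `adaptation_state`.
#' @export
update_state <- function(state, planned_direction, actual_direction, error,
                         field_sign, params) {
  stopifnot(inherits(params, "learning_params"),
            field_sign %in% c(-1, 0, 1))
  v <- params$retention * state$value
  if (field_sign != 0) {
    ref <- if (params$hypothesis == "PRL") planned_direction else actual_direction
    g <- primitive_activation(state$direction - ref, params$primitive_sigma)
    k <- params$gain * if (field_sign > 0) params$cw_gain_scale else 1
    v <- v + wrap_angle(error) * k * g
  }
  as_adaptation_state(state$direction, v)
}

#' Closed-form state after a trial history
#'
#' Analytic solution of the linear recursion: the state after `n` trials is
#' the geometric-decay superposition
#' `x_n(theta) = sum_k A^(n-1-k) e_k k_k g(theta - theta_ref_k)`,
#' over force-field trials `k` (null and clamp trials contribute only decay).
#' Serves as an independent check on iterated [update_state()].
#'
#' @param history A data frame with columns `planned`, `actual`, `error`
#'   (degrees) and `field_sign` (+1/-1/0), one row per trial in order.
#' @param params A [learning_params()].
#' @param grid_step Grid spacing in degrees.
#' @return The `adaptation_state` after the full history.
#' @export
closed_form_state <- function(history, params, grid_step = 1) {
  state <- adaptation_state(grid_step)
  n <- nrow(history)
  if (n == 0L) return(state)
  v <- state$value
  A <- params$retention
  for (k in seq_len(n)) {
    if (history$field_sign[k] == 0) next
    ref <- if (params$hypothesis == "PRL") history$planned[k] else history$actual[k]
    gk <- params$gain *
      if (history$field_sign[k] > 0) params$cw_gain_scale else 1
    g <- primitive_activation(state$direction - ref, params$primitive_sigma)
    v <- v + A^(n - k) * wrap_angle(history$error[k]) * gk * g
  }
  as_adaptation_state(state$direction, v)
}

#' Predicted generalization pattern from an adaptation state
#'
#' State values at the probe directions expressed as a fraction of a
#' reference field strength: `state_at(probe) / |reference_viscosity|`.
#' Positive values are compensation appropriate for the CCW field, the
#' conventional axis for these patterns.
#'
#' @param state An [adaptation_state()].
#' @param probe_directions Probe directions in degrees.
#' @param reference_viscosity Reference field viscosity, N/(m/s); must be
#'   non-zero (its magnitude scales the pattern).
#' @return A tibble with columns `direction` and `adaptation`
#'   (dimensionless).
#' @export
predicted_generalization <- function(state, probe_directions,
                                     reference_viscosity) {
  if (!is.numeric(reference_viscosity) || reference_viscosity == 0) {
    stop("`reference_viscosity` must be non-zero", call. = FALSE)
  }
  tibble::tibble(direction = wrap_angle(probe_directions),
                 adaptation = state_at(state, probe_directions) /
                   abs(reference_viscosity))
}

#' Serialize an adaptation state to CSV
#'
#' Columns `direction_deg`, `compensation_N_per_m_per_s`.
#' @param state An [adaptation_state()].
#' @param path File path.
#' @export
write_adaptation_state <- function(state, path) {
  readr::write_csv(
    tibble::tibble(direction_deg = state$direction,
                   compensation_N_per_m_per_s = state$value),
    path)
  invisible(path)
}
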