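# Closed-loop coupling of the learning rule to movement outcomes.
#
# Each trial is summarized by its initial movement direction (reaches are
# approximately straight over the portion of the movement that matters for
# velocity-dependent dynamics). On a force-field trial the uncompensated
# viscosity maps to a directional error through a static gain plus Gaussian
# motor noise; the error drives the next state update. Error-clamp trials
# are idealized (lateral displacement exactly zero): the planned direction
# is achieved, the state decays, and the compensatory lateral force the
# subject would press into the channel is synthesized from the state and
# the reference speed profile.

#' Closed-loop simulation configuration
#'
#' @param error_gain Degrees of initial-direction error per N/(m/s) of
#'   uncompensated viscosity (>= 0). The default 1.4 deg/(N/(m/s)) places
#'   the mean CW/CCW error separation of the interference paradigm near the
#'   25-degree anchor; [calibrate_error_gain()] refines it.
#' @param motor_noise_sd SD of Gaussian motor noise added to every movement
#'   direction, degrees (default 3).
#' @param reference_viscosity Signed viscosity, N/(m/s), of the field against
#'   which error-clamp adaptation coefficients are expressed (default -9,
#'   the CCW field, giving the conventional CCW-positive pattern axis).
#' @param grid_step Adaptation-state grid spacing, degrees.
#' @param reach_distance,reach_duration,dt Reference reach kinematics passed
#'   to [min_jerk_trajectory()] when clamp forces are synthesized.
#' @param store_clamp_traces If `TRUE`, error-clamp trial records carry the
#'   full lateral-force time series as a list column (default `FALSE`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(error_gain = 1.4,
                       motor_noise_sd = 3,
                       reference_viscosity = -9,
                       grid_step = 1,
                       reach_distance = 0.1,
                       reach_duration = 0.621,
                       dt = 0.005,
                       store_clamp_traces = FALSE) {
  if (!is.numeric(error_gain) || error_gain < 0) {
    stop("`error_gain` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(motor_noise_sd) || motor_noise_sd < 0) {
    stop("`motor_noise_sd` must be >= 0", call. = FALSE)
  }
  if (reference_viscosity == 0) {
    stop("`reference_viscosity` must be non-zero", call. = FALSE)
  }
  structure(list(error_gain = error_gain, motor_noise_sd = motor_noise_sd,
                 reference_viscosity = reference_viscosity,
                 grid_step = grid_step, reach_distance = reach_distance,
                 reach_duration = reach_duration, dt = dt,
                 store_clamp_traces = store_clamp_traces),
            class = "sim_config")
}

#' Lateral force pressed into an error-clamp channel
#'
#' The compensatory lateral force a subject with adaptation state `state`
#' produces during a clamped reach along `probe_direction`:
#' `state_at(probe) * speed(t)`, on the lateral axis oriented so that
#' positive force is compensation appropriate for the CCW field. Bell-shaped
#' for a minimum-jerk reach; a state of 9 N/(m/s) at peak speed 0.3 m/s
#' presses 2.7 N at mid-movement, mirroring the field it compensates.
#'
#' @param state An [adaptation_state()].
#' @param probe_direction Probe direction, degrees.
#' @param traj Reference trajectory along the probe direction
#'   ([min_jerk_trajectory()]).
#' @return Tibble with columns `t` (s), `speed` (m/s), `force` (N).
#' @export
measured_clamp_force <- function(state, probe_direction, traj) {
  sp <- sqrt(traj$vx^2 + traj$vy^2)
  tibble::tibble(t = traj$t, speed = sp,
                 force = state_at(state, probe_direction) * sp)
}

# internal: one trial, using the current RNG stream via pre-drawn noise
step_trial <- function(state, target, field_mode, viscosity, params, cfg,
                       noise) {
  planned <- wrap_angle(target)
  if (field_mode == "clamp") {
    actual <- planned
    error <- NA_real_
    field_sign <- 0
    coef <- -state_at(state, planned) / cfg$reference_viscosity
    new_state <- update_state(state, planned, actual, 0, 0, params)
  } else if (field_mode == "null") {
    error <- noise
    actual <- wrap_angle(planned + error)
    field_sign <- 0
    coef <- NA_real_
    new_state <- update_state(state, planned, actual, error, 0, params)
  } else if (field_mode == "curl") {
    field_sign <- sign(viscosity)
    error <- -cfg$error_gain * (viscosity + state_at(state, planned)) + noise
    actual <- wrap_angle(planned + error)
    coef <- NA_real_
    new_state <- update_state(state, planned, actual, error, field_sign, params)
  } else {
    stop("unknown field_mode: ", field_mode, call. = FALSE)
  }
  list(planned = planned, actual = actual, error = error,
       field_sign = field_sign, adaptation_at_probe = coef,
       state = new_state)
}

#' Simulate a single trial
#'
#' Applies the closed-loop error model and the state update for one trial.
#' On curl-field trials the directional error is
#' `-error_gain * (B + state(target)) + noise`, so a naive subject in the CW
#' (positive-B) field errs toward smaller angles and the error shrinks as
#' the state converges on full compensation (`state = -B`). Null trials have
#' pure noise errors; error-clamp trials achieve the planned direction
#' exactly, decay the state, and report the adaptation coefficient (and,
#' optionally, the lateral channel force).
#'
#' @param state An [adaptation_state()].
#' @param target Target direction, degrees.
#' @param field_mode `"curl"`, `"null"` or `"clamp"`.
#' @param viscosity Signed field viscosity, N/(m/s) (ignored unless
#'   `field_mode = "curl"`).
#' @param params A [learning_params()].
#' @param cfg A [sim_config()].
#' @return A list with `record` (one-row tibble: `target`, `field_mode`,
#'   `viscosity`, `field_sign`, `planned`, `actual`, `error`,
#'   `adaptation_at_probe`) and `state` (the updated state).
#' @export
simulate_trial <- function(state, target, field_mode = c("curl", "null", "clamp"),
                           viscosity = 0, params = learning_params(),
                           cfg = sim_config()) {
  field_mode <- match.arg(field_mode)
  noise <- stats::rnorm(1L, 0, cfg$motor_noise_sd)
  st <- step_trial(state, target, field_mode, viscosity, params, cfg, noise)
  record <- tibble::tibble(
    target = wrap_angle(target), field_mode = field_mode,
    viscosity = viscosity, field_sign = st$field_sign,
    planned = st$planned, actual = st$actual, error = st$error,
    adaptation_at_probe = st$adaptation_at_probe)
  list(record = record, state = st$state)
}

#' Simulate a full experiment schedule
#'
#' Runs [simulate_trial()] sequentially over a schedule, threading the
#' adaptation state and a single seeded RNG stream, so the output is
#' deterministic given (schedule, params, cfg, seed).
#'
#' @param schedule A schedule tibble (see [interference_schedule()],
#'   [shifted_schedules()]) with columns `trial`, `phase`, `target`,
#'   `field_mode`, `viscosity`.
#' @param params A [learning_params()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed for the trial noise stream, or `NULL` to use the
#'   current RNG state.
#' @param record_state_trials Optional integer vector of trial indices at
#'   which to snapshot the adaptation state (snapshot taken before the
#'   trial's update).
#' @return A tibble of trial records (schedule columns plus `planned`,
#'   `actual`, `error`, `field_sign`, `adaptation_at_probe`, and
#'   `clamp_force` list column if `cfg$store_clamp_traces`), with attributes
#'   `final_state`, `recorded_states` (named list), `params`, `config`,
#'   `seed`.
#' @export
simulate_experiment <- function(schedule, params = learning_params(),
                                cfg = sim_config(), seed = NULL,
                                record_state_trials = NULL) {
  stopifnot(nrow(schedule) > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(schedule)
  noise <- stats::rnorm(n, 0, cfg$motor_noise_sd)
  # hot loop on raw vectors (equivalent to iterating simulate_trial)
  gs <- cfg$grid_step
  grid <- seq(-180, 180 - gs, by = gs)
  ng <- length(grid)
  v <- numeric(ng)
  A <- params$retention
  two_sig2 <- 2 * params$primitive_sigma^2
  prl <- params$hypothesis == "PRL"
  tg <- wrap_angle(schedule$target)
  mode <- schedule$field_mode
  visc <- schedule$viscosity
  read_at <- function(d) {
    d <- wrap_angle(d); if (d == 180) d <- -180
    i0 <- floor((d + 180) / gs)
    fr <- (d + 180) / gs - i0
    v[i0 + 1L] * (1 - fr) + v[(i0 + 1L) %% ng + 1L] * fr
  }
  planned <- tg
  actual <- error <- coef <- rep(NA_real_, n)
  field_sign <- numeric(n)
  snapshots <- list()
  traces <- if (isTRUE(cfg$store_clamp_traces)) vector("list", n) else NULL
  ref_traj <- min_jerk_trajectory(90, cfg$reach_distance, cfg$reach_duration,
                                  cfg$dt)
  ref_speed <- sqrt(ref_traj$vx^2 + ref_traj$vy^2)
  for (i in seq_len(n)) {
    if (!is.null(record_state_trials) && i %in% record_state_trials) {
      snapshots[[as.character(i)]] <- as_adaptation_state(grid, v)
    }
    if (mode[i] == "clamp") {
      actual[i] <- planned[i]
      coef[i] <- -read_at(planned[i]) / cfg$reference_viscosity
      if (!is.null(traces)) {
        traces[[i]] <- tibble::tibble(t = ref_traj$t, speed = ref_speed,
                                      force = read_at(planned[i]) * ref_speed)
      }
      v <- A * v
    } else if (mode[i] == "null") {
      error[i] <- noise[i]
      actual[i] <- wrap_angle(planned[i] + error[i])
      v <- A * v
    } else {
      fs <- sign(visc[i])
      field_sign[i] <- fs
      e <- -cfg$error_gain * (visc[i] + read_at(planned[i])) + noise[i]
      error[i] <- e
      actual[i] <- wrap_angle(planned[i] + e)
      ref <- if (prl) planned[i] else actual[i]
      k <- params$gain * if (fs > 0) params$cw_gain_scale else 1
      dd <- (grid - ref + 180) %% 360 - 180
      v <- A * v + e * k * exp(-dd * dd / two_sig2)
    }
  }
  out <- dplyr::mutate(tibble::as_tibble(schedule),
                       planned = planned, actual = actual, error = error,
                       field_sign = field_sign, adaptation_at_probe = coef)
  if (!is.null(traces)) out$clamp_force <- traces
  structure(out, final_state = as_adaptation_state(grid, v),
            recorded_states = snapshots,
            params = params, config = cfg, seed = seed,
            class = c("trial_table", class(out)))
}

#' Final adaptation state of a simulated experiment
#'
#' @param records A tibble returned by [simulate_experiment()].
#' @return The `adaptation_state` after the last trial.
#' @export
final_state <- function(records) {
  attr(records, "final_state")
}

#' State snapshots recorded during a simulated experiment
#'
#' @param records A tibble returned by [simulate_experiment()].
#' @return Named list of `adaptation_state`s keyed by trial index.
#' @export
recorded_states <- function(records) {
  attr(records, "recorded_states")
}
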