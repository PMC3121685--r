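# Parameter recovery: fit (retention, gain, primitive width) to a synthetic
# cohort's error-clamp series and end-of-training generalization probes by
# nonlinear least squares against noise-free model predictions.

#' Single-target schedule with a final generalization probe block
#'
#' The STT schedule of [shifted_schedules()] followed by a block of
#' consecutive error-clamp probes across a set of directions, giving the
#' directional information needed to identify the primitive width.
#'
#' @param desired_dir Training direction, degrees.
#' @param probe_dirs Probe directions for the final testing block.
#' @param probes_per_dir Clamp trials per probe direction.
#' @param ... Passed to [shifted_schedules()].
#' @return A schedule tibble.
#' @export
stt_generalization_schedule <- function(desired_dir = 90,
                                        probe_dirs = seq(0, 180, by = 22.5),
                                        probes_per_dir = 2L, ...) {
  stt <- shifted_schedules(desired_dir = desired_dir, smoothed_errors = 0,
                           ...)$STT
  probes <- rep(probe_dirs, each = probes_per_dir)
  tail <- tibble::tibble(
    trial = max(stt$trial) + seq_along(probes),
    phase = "testing", target = wrap_angle(probes),
    field_mode = "clamp", viscosity = 0)
  out <- dplyr::bind_rows(tibble::as_tibble(stt), tail)
  attributes(out)[c("paradigm", "desired_dir", "p_ec", "viscosity",
                    "seed")] <-
    attributes(stt)[c("paradigm", "desired_dir", "p_ec", "viscosity",
                      "seed")]
  out
}

# predicted clamp coefficients for one schedule under candidate params
predict_clamp_coefs <- function(schedule, params, cfg) {
  cfg$motor_noise_sd <- 0
  rec <- simulate_experiment(schedule, params, cfg, seed = 1L)
  rec$adaptation_at_probe[rec$field_mode == "clamp"]
}

#' Recover learning parameters from a synthetic cohort
#'
#' Least-squares fit of (retention, gain, primitive width) to the
#' error-clamp adaptation coefficients of a cohort: for candidate
#' parameters, each subject's schedule is re-simulated noise-free and the
#' predicted clamp series is compared with the observed one; the summed
#' squared residual is minimized by Nelder-Mead over transformed
#' parameters (logit retention, log gain, log sigma).
#'
#' @param cohort A [generate_cohort()] table whose schedules include probes
#'   at several directions (see [stt_generalization_schedule()]).
#' @param cfg The [sim_config()] used to generate the cohort (subject-level
#'   error-gain jitter is not modelled; the shared value is used).
#' @param start A [learning_params()] giving the starting point.
#' @param grid_step State grid spacing used during fitting (coarser grids
#'   are faster; default 2 degrees).
#' @return A `learning_params` with the fitted values, plus attributes
#'   `objective` (residual sum of squares) and `convergence`.
#' @export
fit_learning_params <- function(cohort, cfg = sim_config(),
                                start = learning_params(retention = 0.95,
                                                        gain = 0.05,
                                                        primitive_sigma = 30),
                                grid_step = 2) {
  schedules <- attr(cohort, "schedules")
  hypothesis <- start$hypothesis
  cfg$grid_step <- grid_step
  obs <- cohort |>
    dplyr::filter(.data$field_mode == "clamp") |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(coefs = list(.data$adaptation_at_probe),
                     .groups = "drop")
  objective <- function(theta) {
    p <- learning_params(retention = stats::plogis(theta[1L]),
                         gain = exp(theta[2L]),
                         primitive_sigma = exp(theta[3L]),
                         hypothesis = hypothesis)
    sse <- 0
    for (i in seq_len(nrow(obs))) {
      pred <- predict_clamp_coefs(schedules[[obs$subject[i]]], p, cfg)
      sse <- sse + sum((obs$coefs[[i]] - pred)^2)
    }
    sse
  }
  theta0 <- c(stats::qlogis(start$retention), log(start$gain),
              log(start$primitive_sigma))
  opt <- stats::optim(theta0, objective, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-6))
  out <- learning_params(retention = stats::plogis(opt$par[1L]),
                         gain = exp(opt$par[2L]),
                         primitive_sigma = exp(opt$par[3L]),
                         hypothesis = hypothesis)
  attr(out, "objective") <- opt$value
  attr(out, "convergence") <- opt$convergence
  out
}
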