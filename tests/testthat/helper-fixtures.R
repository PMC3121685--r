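# shared fixtures: small schedules and parameter sets used across tests

quiet_cfg <- function(...) sim_config(motor_noise_sd = 0, ...)

# a short mixed schedule exercising all three trial modes
mixed_schedule <- function(n_ff = 20, target = 90, viscosity = 9) {
  modes <- rep(c("curl", "null", "clamp"), length.out = n_ff)
  tibble::tibble(
    trial = seq_len(n_ff),
    phase = "training",
    target = target,
    field_mode = modes,
    viscosity = ifelse(modes == "curl",
                       viscosity * rep(c(1, -1), length.out = n_ff), 0))
}

# random trial history for the closed-form oracle tests
random_history <- function(n, seed) {
  set.seed(seed)
  planned <- runif(n, -180, 180)
  err <- rnorm(n, 0, 15)
  fs <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
  err[fs == 0] <- 0
  tibble::tibble(planned = planned,
                 actual = wrap_angle(planned + err),
                 error = err, field_sign = fs)
}
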