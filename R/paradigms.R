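# Trial-schedule generators: the force-field interference paradigm
# (alternating CW/CCW blocks with interleaved generalization testing) and
# the single-target / shifted-target training paradigms built from a
# smoothed error history.

default_baseline_dirs <- function(train_dir) {
  if (isTRUE(all.equal(wrap_angle(train_dir), wrap_angle(270)))) {
    c(180, 210, 240, 245, 270, 285, 300, 330, 360)
  } else {
    c(-30, 0, 30, 45, 60, 75, 90, 120, 150)
  }
}

schedule_tibble <- function(phase, target, field_mode, viscosity) {
  tibble::tibble(trial = seq_along(phase), phase = phase,
                 target = wrap_angle(target), field_mode = field_mode,
                 viscosity = viscosity)
}

# spread n trials as evenly as possible over dirs, seeded shuffle
spread_trials <- function(n, dirs) {
  base <- rep(dirs, n %/% length(dirs))
  extra <- sample(dirs, n %% length(dirs))
  sample(c(base, extra))
}

#' Force-field interference training schedule
#'
#' Builds the interference paradigm: a baseline of null-field reaches over
#' nine directions, then 672 force-field trials at a single training
#' direction in short alternating CW/CCW blocks, with a 40-trial error-clamp
#' testing block (spread over the nine baseline directions) after every 168
#' training trials. Block lengths realize "7 +/- 2": each 14-trial cycle
#' pairs a CW block of `ratio[1] + j` trials with a CCW block of
#' `ratio[2] - j` trials, `j` drawn uniformly from the largest range keeping
#' both lengths in 5..9; consecutive cycles use `+j` then `-j` so the CW:CCW
#' ratio is exact over every cycle pair (for the 5:9 ratio `j = 0` is
#' forced, so counts are exact per cycle). The field of the final block
#' before each testing block is balanced (CCW, CW, CCW, CW) across the four
#' testing blocks.
#'
#' @param train_dir Training direction, degrees (default 270).
#' @param baseline_dirs The nine baseline/testing directions; defaults to
#'   the direction set associated with `train_dir`.
#' @param ratio_cw_ccw Integer pair of per-cycle CW and CCW trial counts;
#'   must sum to 14 (7:7, 6:8 or 5:9 in the study designs).
#' @param viscosity Magnitude of the field viscosity, N/(m/s) (CW `+`,
#'   CCW `-`); default 9.
#' @param n_baseline Number of baseline trials (default 254), distributed
#'   as evenly as possible over `baseline_dirs` with a seeded shuffle.
#' @param seed Integer seed making the schedule reproducible.
#' @return A schedule tibble with columns `trial`, `phase`
#'   (baseline/training/testing), `target`, `field_mode`
#'   (null/curl/clamp), `viscosity`, `block`, and attributes
#'   `training_direction`, `baseline_dirs`, `ratio`, `seed`, `paradigm`.
#' @export
interference_schedule <- function(train_dir = 270,
                                  baseline_dirs = default_baseline_dirs(train_dir),
                                  ratio_cw_ccw = c(7, 7),
                                  viscosity = 9,
                                  n_baseline = 254,
                                  seed = 1L) {
  if (length(ratio_cw_ccw) != 2L || sum(ratio_cw_ccw) != 14L) {
    stop("`ratio_cw_ccw` must be two counts summing to 14", call. = FALSE)
  }
  if (length(baseline_dirs) != 9L) {
    stop("`baseline_dirs` must hold nine directions", call. = FALSE)
  }
  set.seed(seed)
  n_cw <- ratio_cw_ccw[1L]; n_ccw <- ratio_cw_ccw[2L]
  # admissible block-length jitter keeping both blocks in 5..9
  j_max <- min(9 - n_cw, n_cw - 5, 9 - n_ccw, n_ccw - 5)
  phase <- character(0); target <- numeric(0)
  mode <- character(0); visc <- numeric(0); block <- integer(0)
  add <- function(ph, tg, md, vs, bl) {
    phase <<- c(phase, ph); target <<- c(target, tg)
    mode <<- c(mode, md); visc <<- c(visc, vs)
    block <<- c(block, bl)
  }
  # baseline
  bl_targets <- spread_trials(n_baseline, baseline_dirs)
  add(rep("baseline", n_baseline), bl_targets, rep("null", n_baseline),
      rep(0, n_baseline), rep(0L, n_baseline))
  blk <- 0L
  cycles_per_segment <- 12L  # 12 x 14 = 168 training trials per segment
  for (segment in 1:4) {
    first_cw <- segment %% 2L == 1L  # last blocks: CCW, CW, CCW, CW
    pool <- seq(-j_max, j_max, by = 1L)
    jitter <- rep(pool[sample.int(length(pool), cycles_per_segment / 2L,
                                  replace = TRUE)], each = 2L) * c(1L, -1L)
    for (cyc in seq_len(cycles_per_segment)) {
      len_cw <- n_cw + jitter[cyc]; len_ccw <- n_ccw - jitter[cyc]
      fields <- if (first_cw) list(c(1, len_cw), c(-1, len_ccw))
                else list(c(-1, len_ccw), c(1, len_cw))
      for (f in fields) {
        blk <- blk + 1L
        k <- f[2L]
        add(rep("training", k), rep(train_dir, k), rep("curl", k),
            rep(f[1L] * viscosity, k), rep(blk, k))
      }
    }
    # testing block: 40 consecutive error-clamp trials over the 9 directions
    tst <- spread_trials(40L, baseline_dirs)
    add(rep("testing", 40L), tst, rep("clamp", 40L), rep(0, 40L),
        rep(0L, 40L))
  }
  out <- schedule_tibble(phase, target, mode, visc)
  out$block <- block
  structure(out, training_direction = wrap_angle(train_dir),
            baseline_dirs = wrap_angle(baseline_dirs),
            ratio = ratio_cw_ccw, viscosity = viscosity, seed = seed,
            paradigm = "interference")
}

#' Smooth a mean error history with an exponential-decay fit
#'
#' Least-squares fit of the two-parameter model `a * exp(-n / tau)` to a
#' per-trial mean error series, returning the fitted curve at every trial.
#' Constant series are handled by the large-`tau` limit of the same model.
#'
#' @param mean_errors Numeric vector of mean directional errors per trial,
#'   degrees (>= 3 values).
#' @param trials Trial indices the errors belong to (defaults to
#'   consecutive trials); gaps are allowed, e.g. when probe trials carry no
#'   error.
#' @param eval_trials Trial indices at which to evaluate the fitted curve
#'   (default: `trials`).
#' @return Numeric vector of the fitted curve at `eval_trials`, with
#'   attributes `a` and `tau`.
#' @export
smooth_error_history <- function(mean_errors,
                                 trials = seq_along(mean_errors),
                                 eval_trials = trials) {
  y <- as.numeric(mean_errors)
  keep <- is.finite(y)
  y <- y[keep]
  idx <- as.numeric(trials)[keep]
  n <- length(y)
  if (n < 3L) stop("need at least 3 trials to smooth", call. = FALSE)
  sse_fit <- function(tau) {
    w <- exp(-idx / tau)
    a <- sum(w * y) / sum(w * w)
    c(a = a, sse = sum((y - a * w)^2))
  }
  # coarse grid over tau, then local refinement; robust for flat inputs
  taus <- exp(seq(log(0.5), log(200 * max(idx)), length.out = 80))
  grid <- vapply(taus, function(tt) sse_fit(tt)["sse"], numeric(1))
  tau0 <- taus[which.min(grid)]
  opt <- stats::optimize(function(tt) sse_fit(tt)["sse"],
                         interval = c(tau0 / 4, tau0 * 4))
  tau <- opt$minimum
  a <- sse_fit(tau)["a"]
  # refine jointly with Levenberg-Marquardt when the surface is well-behaved
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-idx / tau),
                      start = list(a = unname(a), tau = tau),
                      lower = c(-Inf, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    if (sum(stats::resid(fit)^2) <= sse_fit(tau)["sse"] + 1e-12) {
      a <- co[["a"]]; tau <- co[["tau"]]
    }
  }
  structure(unname(a) * exp(-as.numeric(eval_trials) / tau),
            a = unname(a), tau = unname(tau))
}

#' Single-target and shifted-target training schedules
#'
#' Builds the three matched training paradigms used to compare credit
#' assignment hypotheses: STT (all targets at the desired learning
#' direction), LST (targets shifted opposite the expected error so the
#' actual motion lines up with the desired direction:
#' `target_n = desired - smoothed_error_n`), and RST (the mirror image,
#' `target_n = desired + smoothed_error_n`). Each schedule has a baseline of
#' null-field reaches and a force-field training period, with error-clamp
#' probes at the desired direction interspersed at probability `p_ec`; the
#' probe positions are drawn once and shared by the three schedules so
#' matched-seed comparisons are paired.
#'
#' @param desired_dir Desired learning direction, degrees (default 90).
#' @param smoothed_errors Expected per-trial directional errors, degrees
#'   (e.g. from [smooth_error_history()]); recycled from its last value if
#'   shorter than the training period.
#' @param p_ec Probability that a trial is an error-clamp probe, in (0, 1).
#' @param viscosity Signed training-field viscosity, N/(m/s) (default
#'   +22.5, clockwise).
#' @param n_baseline,n_training Trial counts (defaults 75 and 125).
#' @param seed Integer seed for the probe placement.
#' @return Named list of schedule tibbles `STT`, `LST`, `RST`, each with the
#'   columns of [interference_schedule()] (without `block`) and attributes
#'   `paradigm`, `desired_dir`, `p_ec`, `seed`.
#' @export
shifted_schedules <- function(desired_dir = 90, smoothed_errors,
                              p_ec = 0.2, viscosity = 22.5,
                              n_baseline = 75, n_training = 125,
                              seed = 1L) {
  if (!(p_ec > 0 && p_ec < 1)) stop("`p_ec` must be in (0, 1)", call. = FALSE)
  s <- as.numeric(smoothed_errors)
  if (length(s) < n_training) {
    s <- c(s, rep(s[length(s)], n_training - length(s)))
  }
  s <- s[seq_len(n_training)]
  set.seed(seed)
  ec_base <- stats::runif(n_baseline) < p_ec
  ec_train <- stats::runif(n_training) < p_ec
  build <- function(shift_sign, name) {
    targets_train <- wrap_angle(desired_dir + shift_sign * s)
    tg <- c(rep(desired_dir, n_baseline),
            ifelse(ec_train, desired_dir, targets_train))
    md <- c(ifelse(ec_base, "clamp", "null"),
            ifelse(ec_train, "clamp", "curl"))
    vs <- c(rep(0, n_baseline), ifelse(ec_train, 0, viscosity))
    ph <- c(rep("baseline", n_baseline), rep("training", n_training))
    out <- schedule_tibble(ph, tg, md, vs)
    structure(out, paradigm = name, desired_dir = wrap_angle(desired_dir),
              p_ec = p_ec, viscosity = viscosity, seed = seed)
  }
  list(STT = build(0, "STT"), LST = build(-1, "LST"), RST = build(1, "RST"))
}

#' Mean CW/CCW movement-direction separation in a trial table
#'
#' The separation between the mean actual movement directions (equivalently,
#' mean errors, since the planned direction is fixed) experienced on CCW-
#' versus CW-field training trials.
#'
#' @param records A trial table from [simulate_experiment()].
#' @return Separation in degrees.
#' @export
error_separation <- function(records) {
  tr <- dplyr::filter(records, .data$field_mode == "curl")
  mean(tr$error[tr$field_sign < 0]) - mean(tr$error[tr$field_sign > 0])
}

#' Calibrate the closed-loop error gain
#'
#' Adjusts `error_gain` so that a noise-free simulation of `schedule`
#' reproduces a target separation between the mean movement directions in
#' the CW and CCW fields (the study anchor is about 25 degrees). Because
#' within-block adaptation shrinks errors below their naive value, the
#' calibrated gain is somewhat larger than `target / (2 * viscosity)`.
#'
#' @param schedule A schedule with both field directions (e.g.
#'   [interference_schedule()]).
#' @param params A [learning_params()].
#' @param cfg A [sim_config()] providing the starting `error_gain`.
#' @param target_separation Target mean-direction separation, degrees.
#' @param iterations Fixed-point iterations (default 4).
#' @return A `sim_config` identical to `cfg` but with the calibrated
#'   `error_gain`.
#' @export
calibrate_error_gain <- function(schedule, params = learning_params(),
                                 cfg = sim_config(),
                                 target_separation = 25,
                                 iterations = 4) {
  quiet_cfg <- cfg
  quiet_cfg$motor_noise_sd <- 0
  for (i in seq_len(iterations)) {
    rec <- simulate_experiment(schedule, params, quiet_cfg, seed = 1L)
    sep <- error_separation(rec)
    if (!is.finite(sep) || sep <= 0) {
      stop("cannot calibrate: schedule produced no usable field trials",
           call. = FALSE)
    }
    quiet_cfg$error_gain <- quiet_cfg$error_gain * target_separation / sep
  }
  cfg$error_gain <- quiet_cfg$error_gain
  cfg
}
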