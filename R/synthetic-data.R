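# Synthetic "raw" subject datasets: closed-loop simulation plus per-trial
# kinematic summaries (and optional 200-Hz traces) with noise, so the whole
# analysis pipeline -- inclusion filtering included -- runs on generated
# data. Includes an impaired-subject preset with a lower learning gain and
# higher motor noise, the signature of adaptation in chronic stroke.

#' Subject profile for the synthetic-data generator
#'
#' Bundles the learning parameters, simulation configuration and kinematic
#' nuisance parameters that define one simulated subject population. The
#' `"impaired"` preset halves the learning gain and doubles the motor noise
#' relative to the supplied values, giving slower learning and higher
#' residual errors; its exact numbers are synthetic placeholders for a
#' patient population, not fitted values.
#'
#' @param label `"healthy"` or `"impaired"`.
#' @param params A [learning_params()].
#' @param config A [sim_config()].
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters
#'   (median `exp(rt_meanlog)` = 0.3 s by default).
#' @param duration_sd SD of the per-trial movement duration around the
#'   reference duration, s.
#' @param speed_outlier_rate,rt_outlier_rate Probability that a trial's
#'   peak speed / reaction time is replaced by an out-of-bounds value, to
#'   exercise the inclusion filter.
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(label = c("healthy", "impaired"),
                            params = learning_params(),
                            config = sim_config(),
                            rt_meanlog = log(0.3), rt_sdlog = 0.35,
                            duration_sd = 0.035,
                            speed_outlier_rate = 0.015,
                            rt_outlier_rate = 0.015) {
  label <- match.arg(label)
  if (label == "impaired") {
    params$gain <- params$gain * 0.5
    config$motor_noise_sd <- config$motor_noise_sd * 2
  }
  structure(list(label = label, params = params, config = config,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 duration_sd = duration_sd,
                 speed_outlier_rate = speed_outlier_rate,
                 rt_outlier_rate = rt_outlier_rate),
            class = "subject_profile")
}

# smooth (moving-average low-passed) positional jitter, SD in metres
smooth_jitter <- function(n, sd = 0.001, k = 9L) {
  if (n < k + 2L) return(rep(0, n))
  raw <- stats::rnorm(n + k)
  sm <- stats::filter(raw, rep(1 / k, k), sides = 2)
  sm <- sm[!is.na(sm)][seq_len(n)]
  sm <- sm - mean(sm)
  s <- stats::sd(sm)
  if (s == 0) rep(0, n) else sm / s * sd
}

#' Generate one synthetic subject dataset
#'
#' Runs the closed-loop simulation over a schedule and renders the outcome
#' as a raw-looking trial table: per-trial movement duration, peak speed
#' and reaction time (with configurable out-of-bounds outliers so the
#' inclusion filter has work to do), and optionally full 200-Hz kinematic
#' and force traces per trial.
#'
#' @param profile A [subject_profile()].
#' @param schedule A schedule tibble.
#' @param seed Integer seed; the dataset is deterministic given
#'   (profile, schedule, seed).
#' @param keep_traces If `TRUE`, attach per-trial trajectory and force
#'   tibbles as list columns (`trace`), with smooth 1-mm positional jitter;
#'   error-clamp trials also carry their lateral channel force
#'   (`clamp_force`).
#' @return A trial table (as [simulate_experiment()]) with kinematic
#'   columns `movement_duration`, `peak_speed`, `reaction_time` and
#'   attributes `profile` and `seed`.
#' @export
generate_subject <- function(profile, schedule, seed = 1L,
                             keep_traces = FALSE) {
  stopifnot(inherits(profile, "subject_profile"))
  cfg <- profile$config
  cfg$store_clamp_traces <- isTRUE(keep_traces)
  # snapshot the state at the entry of each testing block (if any)
  tst <- which(schedule$phase == "testing")
  starts <- tst[c(TRUE, diff(tst) > 1L)]
  rec <- simulate_experiment(schedule, profile$params, cfg, seed = seed,
                             record_state_trials = starts)
  n <- nrow(rec)
  # kinematic summaries (RNG continues the seeded stream)
  dur <- pmax(stats::rnorm(n, cfg$reach_duration, profile$duration_sd), 0.35)
  sp <- 1.875 * cfg$reach_distance / dur
  rt <- stats::rlnorm(n, profile$rt_meanlog, profile$rt_sdlog)
  sp_out <- stats::runif(n) < profile$speed_outlier_rate
  rt_out <- stats::runif(n) < profile$rt_outlier_rate
  sp[sp_out] <- ifelse(stats::runif(sum(sp_out)) < 0.5,
                       stats::runif(sum(sp_out), 0.56, 0.75),
                       stats::runif(sum(sp_out), 0.12, 0.19))
  rt[rt_out] <- ifelse(stats::runif(sum(rt_out)) < 0.5,
                       stats::runif(sum(rt_out), 0.01, 0.07),
                       stats::runif(sum(rt_out), 2.6, 4.0))
  rec$movement_duration <- dur
  rec$peak_speed <- sp
  rec$reaction_time <- rt
  if (isTRUE(keep_traces)) {
    rec$trace <- purrr::map(seq_len(n), function(i) {
      traj <- min_jerk_trajectory(rec$actual[i], cfg$reach_distance, dur[i],
                                  cfg$dt)
      m <- nrow(traj)
      traj$x <- traj$x + smooth_jitter(m)
      traj$y <- traj$y + smooth_jitter(m)
      # velocities consistent with the jittered positions by construction
      traj$vx <- c(diff(traj$x) / cfg$dt, 0)
      traj$vy <- c(diff(traj$y) / cfg$dt, 0)
      if (rec$field_mode[i] == "curl") {
        f <- curl_force(cbind(traj$vx, traj$vy), rec$viscosity[i])
        traj$fx <- f[, 1L]; traj$fy <- f[, 2L]
      } else {
        traj$fx <- 0; traj$fy <- 0
      }
      traj
    })
  }
  attr(rec, "profile") <- profile
  attr(rec, "seed") <- seed
  rec
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject seeds are derived deterministically from `master_seed`;
#' subjects receive mild multiplicative jitter on the learning gain and
#' error gain (log-normal, relative SD `jitter_sd`).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param profile A [subject_profile()] shared by the cohort.
#' @param schedule A schedule tibble, or a function `function(seed)`
#'   returning one (so each subject can get a freshly randomized schedule).
#' @param master_seed Integer master seed.
#' @param jitter_sd Relative SD of inter-subject parameter jitter
#'   (default 0.05; 0 disables it).
#' @param keep_traces Passed to [generate_subject()].
#' @return A tibble binding all subjects' trial tables with a leading
#'   `subject` column, and attributes `final_states` (list of
#'   `adaptation_state`), `profiles`, `seeds`, `schedules`.
#' @export
generate_cohort <- function(n_subjects, profile, schedule,
                            master_seed = 1L, jitter_sd = 0.05,
                            keep_traces = FALSE) {
  stopifnot(n_subjects >= 1)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  jg <- exp(stats::rnorm(n_subjects, 0, jitter_sd))
  je <- exp(stats::rnorm(n_subjects, 0, jitter_sd))
  subjects <- vector("list", n_subjects)
  finals <- vector("list", n_subjects)
  recorded <- vector("list", n_subjects)
  profiles <- vector("list", n_subjects)
  schedules <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    pr <- profile
    pr$params$gain <- pr$params$gain * jg[i]
    pr$config$error_gain <- pr$config$error_gain * je[i]
    sch <- if (is.function(schedule)) schedule(seeds[i]) else schedule
    subj <- generate_subject(pr, sch, seed = seeds[i],
                             keep_traces = keep_traces)
    finals[[i]] <- final_state(subj)
    recorded[[i]] <- recorded_states(subj)
    profiles[[i]] <- pr
    schedules[[i]] <- sch
    subj$subject <- i
    subjects[[i]] <- tibble::as_tibble(subj)
  }
  out <- dplyr::bind_rows(subjects)
  out <- dplyr::relocate(out, "subject")
  structure(out, final_states = finals, recorded_states = recorded,
            profiles = profiles, seeds = seeds, schedules = schedules,
            master_seed = master_seed,
            class = c("cohort_table", class(out)))
}

#' Write a subject dataset to a directory
#'
#' One directory per subject: `schedule.csv` (the schedule columns),
#' `trials.csv` (the full trial table without list columns), per-trial
#' trace CSVs under `traces/` when present, and `metadata.json` holding the
#' profile parameters and seed.
#'
#' @param subject Output of [generate_subject()].
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject_dataset <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- subject[, !vapply(subject, is.list, logical(1)), drop = FALSE]
  readr::write_csv(flat[, intersect(c("trial", "phase", "target",
                                      "field_mode", "viscosity", "block"),
                                    names(flat))],
                   file.path(dir, "schedule.csv"))
  readr::write_csv(flat, file.path(dir, "trials.csv"))
  if ("trace" %in% names(subject)) {
    tdir <- file.path(dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    purrr::walk(seq_len(nrow(subject)), function(i) {
      readr::write_csv(subject$trace[[i]],
                       file.path(tdir, sprintf("trial_%04d.csv", i)))
    })
  }
  pr <- attr(subject, "profile")
  meta <- list(label = pr$label,
               params = unclass(pr$params),
               config = unclass(pr$config),
               seed = attr(subject, "seed"))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
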