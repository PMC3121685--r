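# End-to-end in-silico experiments: interference training with
# generalization testing (experiment 1) and the comparison of STT/LST/RST
# training paradigms (experiment 2), each run under both credit-assignment
# hypotheses on synthetic cohorts.

mean_state_of <- function(states) {
  grid <- states[[1L]]$direction
  vals <- rowMeans(vapply(states, function(s) s$value,
                          numeric(length(grid))))
  as_adaptation_state(grid, vals)
}

#' Simulate the force-field interference experiment
#'
#' Simulates a cohort on the interference schedule under the
#' motion-referenced (MRL) and plan-referenced (PRL) learning rules with
#' matched seeds, then runs the generalization analysis: the cohort-mean
#' predicted generalization pattern on a dense grid (from the adaptation
#' states at entry to each testing block), the empirical pattern from the
#' error-clamp probes, the peak-to-trough separation and its comparison
#' with the mean CW/CCW movement-direction separation, and the flatness of
#' the PRL pattern relative to the MRL extremum.
#'
#' @param n_subjects Cohort size (default 12).
#' @param train_dir Training direction, degrees.
#' @param ratio_cw_ccw Per-cycle CW:CCW trial counts (sum 14).
#' @param viscosity Field magnitude, N/(m/s).
#' @param params A [learning_params()]; its `hypothesis` is overridden as
#'   each rule is simulated.
#' @param cfg A [sim_config()].
#' @param calibrate If `TRUE` (default), [calibrate_error_gain()] sets the
#'   error gain so the mean CW/CCW direction separation hits
#'   `target_separation`.
#' @param target_separation Calibration anchor, degrees (default 25).
#' @param jitter_sd Inter-subject parameter jitter.
#' @param seed Master seed.
#' @param out_dir Optional directory to write CSV patterns and a JSON
#'   report into.
#' @return A list of class `exp1_report`: `pattern` (dense cohort-mean
#'   patterns, tibble with `hypothesis`, `direction`, `adaptation`),
#'   `observed` (empirical probe patterns per hypothesis),
#'   `peak_separation`, `peak`, `trough`, `error_separation`,
#'   `prl_flatness` (max |PRL| / max |MRL|), `error_gain`, `n_subjects`,
#'   `seed`.
#' @export
run_exp1 <- function(n_subjects = 12, train_dir = 270,
                     ratio_cw_ccw = c(7, 7), viscosity = 9,
                     params = learning_params(), cfg = sim_config(),
                     calibrate = TRUE, target_separation = 25,
                     jitter_sd = 0.05, seed = 1L, out_dir = NULL) {
  schedule_fn <- function(s) {
    interference_schedule(train_dir = train_dir,
                          ratio_cw_ccw = ratio_cw_ccw,
                          viscosity = viscosity, seed = s)
  }
  params$hypothesis <- "MRL"
  if (isTRUE(calibrate)) {
    cfg <- calibrate_error_gain(schedule_fn(seed), params, cfg,
                                target_separation = target_separation)
  }
  dense <- list(); observed <- list(); seps <- list()
  for (hyp in c("MRL", "PRL")) {
    p <- params; p$hypothesis <- hyp
    profile <- subject_profile("healthy", params = p, config = cfg)
    cohort <- generate_cohort(n_subjects, profile, schedule_fn,
                              master_seed = seed, jitter_sd = jitter_sd)
    states <- unlist(attr(cohort, "recorded_states"), recursive = FALSE)
    mean_state <- mean_state_of(states)
    dg <- predicted_generalization(mean_state, mean_state$direction,
                                   cfg$reference_viscosity)
    dense[[hyp]] <- dplyr::mutate(dg, hypothesis = hyp, .before = 1L)
    obs <- generalization_pattern(
      dplyr::filter(cohort, .data$phase == "testing"))
    observed[[hyp]] <- dplyr::mutate(tibble::as_tibble(obs),
                                     hypothesis = hyp, .before = 1L)
    seps[[hyp]] <- error_separation(cohort)
  }
  mrl <- dense[["MRL"]]; prl <- dense[["PRL"]]
  sep <- peak_separation(mrl, noise_threshold = 0,
                         training_direction = train_dir)
  report <- structure(list(
    pattern = dplyr::bind_rows(dense),
    observed = dplyr::bind_rows(observed),
    peak_separation = as.numeric(sep),
    peak = attr(sep, "peak"), trough = attr(sep, "trough"),
    error_separation = seps[["MRL"]],
    prl_flatness = max(abs(prl$adaptation)) / max(abs(mrl$adaptation)),
    error_gain = cfg$error_gain,
    train_dir = wrap_angle(train_dir), n_subjects = n_subjects,
    seed = seed), class = "exp1_report")
  if (!is.null(out_dir)) write_exp1_report(report, out_dir)
  report
}

write_exp1_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$pattern, file.path(out_dir, "pattern_dense.csv"))
  readr::write_csv(report$observed, file.path(out_dir, "pattern_probes.csv"))
  jsonlite::write_json(
    report[c("peak_separation", "peak", "trough", "error_separation",
             "prl_flatness", "error_gain", "train_dir", "n_subjects",
             "seed")],
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate the training-paradigm comparison experiment
#'
#' Mirrors the staged design: a pilot single-target (STT) cohort is
#' simulated under motion-referenced learning to estimate the mean
#' trial history of directional errors; an exponential-decay smooth of that
#' history defines the left- and right-shifted target sequences
#' ([shifted_schedules()]); then cohorts are simulated on the three
#' paradigms under both hypotheses (matched seeds) and their error-clamp
#' learning curves are summarized early (first three probes) and late
#' (last three probes) in training.
#'
#' @param n_subjects Cohort size per paradigm (default 30).
#' @param n_pilot Pilot STT cohort size used for shift calibration
#'   (default 17).
#' @param desired_dir Desired learning direction, degrees (default 90).
#' @param viscosity Signed training-field viscosity (default +22.5, CW).
#' @param p_ec Error-clamp probe probability (default 0.2).
#' @param params A [learning_params()]; `hypothesis` overridden per rule.
#' @param cfg A [sim_config()]; its `reference_viscosity` is set to the
#'   training field so adaptation coefficients run 0 to 1.
#' @param jitter_sd Inter-subject parameter jitter.
#' @param seed Master seed.
#' @param out_dir Optional directory for CSV/JSON output.
#' @return A list of class `exp2_report`: `curves` (mean learning curve
#'   per hypothesis and paradigm), `summary` (early/late means),
#'   `smoothed_errors`, `orderings` (named logicals for the group-order
#'   predictions), `n_subjects`, `seed`.
#' @export
run_exp2 <- function(n_subjects = 30, n_pilot = 17, desired_dir = 90,
                     viscosity = 22.5, p_ec = 0.2,
                     params = learning_params(), cfg = sim_config(),
                     jitter_sd = 0.05, seed = 1L, out_dir = NULL) {
  cfg$reference_viscosity <- viscosity
  params$hypothesis <- "MRL"
  # pilot STT cohort (MRL) -> mean error history -> smoothed shifts
  pilot_sched <- shifted_schedules(desired_dir, 0, p_ec = p_ec,
                                   viscosity = viscosity, seed = seed)$STT
  n_base <- sum(pilot_sched$phase == "baseline")
  pilot <- generate_cohort(n_pilot,
                           subject_profile("healthy", params = params,
                                           config = cfg),
                           pilot_sched, master_seed = seed,
                           jitter_sd = jitter_sd)
  hist <- pilot |>
    dplyr::filter(.data$phase == "training", .data$field_mode == "curl") |>
    dplyr::mutate(train_trial = .data$trial - n_base) |>
    dplyr::group_by(.data$train_trial) |>
    dplyr::summarise(err = mean(.data$error), .groups = "drop")
  n_train <- sum(pilot_sched$phase == "training")
  smoothed <- smooth_error_history(hist$err, trials = hist$train_trial,
                                   eval_trials = seq_len(n_train))
  schedules <- shifted_schedules(desired_dir, smoothed, p_ec = p_ec,
                                 viscosity = viscosity, seed = seed)
  curves <- list(); summaries <- list()
  for (hyp in c("MRL", "PRL")) {
    p <- params; p$hypothesis <- hyp
    profile <- subject_profile("healthy", params = p, config = cfg)
    for (paradigm in names(schedules)) {
      cohort <- generate_cohort(n_subjects, profile, schedules[[paradigm]],
                                master_seed = seed, jitter_sd = jitter_sd)
      cv <- cohort |>
        dplyr::filter(.data$phase == "training",
                      .data$field_mode == "clamp") |>
        dplyr::group_by(.data$trial) |>
        dplyr::summarise(adaptation = mean(.data$adaptation_at_probe),
                         se = stats::sd(.data$adaptation_at_probe) /
                           sqrt(dplyr::n()),
                         .groups = "drop") |>
        dplyr::arrange(.data$trial) |>
        dplyr::mutate(probe = dplyr::row_number(),
                      hypothesis = hyp, paradigm = paradigm,
                      .before = 1L)
      ls <- learning_summary(cv$adaptation)
      curves[[paste(hyp, paradigm)]] <- cv
      summaries[[paste(hyp, paradigm)]] <- tibble::tibble(
        hypothesis = hyp, paradigm = paradigm,
        early = ls$early, late = ls$late)
    }
  }
  summary <- dplyr::bind_rows(summaries)
  early <- function(h, g) summary$early[summary$hypothesis == h &
                                          summary$paradigm == g]
  late_vals <- function(h) summary$late[summary$hypothesis == h]
  orderings <- c(
    mrl_early_lst_gt_stt = early("MRL", "LST") > early("MRL", "STT"),
    mrl_early_stt_gt_rst = early("MRL", "STT") > early("MRL", "RST"),
    prl_early_stt_gt_lst = early("PRL", "STT") > early("PRL", "LST"),
    prl_early_lst_sim_rst =
      abs(early("PRL", "LST") - early("PRL", "RST")) <
        0.5 * (early("PRL", "STT") - early("PRL", "LST")) + 0.05)
  report <- structure(list(
    curves = dplyr::bind_rows(curves), summary = summary,
    smoothed_errors = as.numeric(smoothed),
    late_spread = sapply(c("MRL", "PRL"),
                         function(h) diff(range(late_vals(h)))),
    orderings = orderings, desired_dir = wrap_angle(desired_dir),
    n_subjects = n_subjects, seed = seed), class = "exp2_report")
  if (!is.null(out_dir)) write_exp2_report(report, out_dir)
  report
}

write_exp2_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$curves, file.path(out_dir, "learning_curves.csv"))
  readr::write_csv(report$summary, file.path(out_dir, "summary.csv"))
  jsonlite::write_json(
    list(orderings = as.list(report$orderings),
         late_spread = as.list(report$late_spread),
         smoothed_errors = report$smoothed_errors,
         desired_dir = report$desired_dir,
         n_subjects = report$n_subjects, seed = report$seed),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.exp1_report <- function(x, ...) {
  cat("Interference-training simulation (", x$n_subjects, " subjects, ",
      "training at ", x$train_dir, " deg)\n", sep = "")
  cat(sprintf("  MRL pattern: peak %+.1f deg, trough %+.1f deg, separation %.1f deg\n",
              x$peak, x$trough, x$peak_separation))
  cat(sprintf("  mean CW/CCW direction separation: %.1f deg (error gain %.3f)\n",
              x$error_separation, x$error_gain))
  cat(sprintf("  PRL flatness (max|PRL| / max|MRL|): %.3f\n", x$prl_flatness))
  invisible(x)
}

#' @export
print.exp2_report <- function(x, ...) {
  cat("Training-paradigm comparison (", x$n_subjects,
      " subjects per group)\n", sep = "")
  print(x$summary)
  cat("group-order predictions:\n")
  print(x$orderings)
  invisible(x)
}
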