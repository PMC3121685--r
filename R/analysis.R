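# Measurement pipeline: adaptation coefficients from error-clamp force
# profiles, trial inclusion filtering, generalization patterns, peak
# separation, pattern correlations and learning-curve summaries.

#' Adaptation coefficient from an error-clamp force profile
#'
#' Ordinary least-squares slope, without intercept, of the measured lateral
#' force regressed on the ideal field-compensating force over the movement:
#' 1 is full compensation, 0 is naive. The regression window and
#' no-intercept convention are set where this is used on whole simulated
#' profiles.
#'
#' @param measured Measured lateral force series, N.
#' @param ideal Ideal compensating force series, N (same length; not
#'   identically zero).
#' @return Dimensionless slope.
#' @examples
#' s <- sin(seq(0, pi, length.out = 50))
#' adaptation_coefficient(0.5 * s, s)   # 0.5
#' @export
adaptation_coefficient <- function(measured, ideal) {
  if (length(measured) != length(ideal)) {
    stop("`measured` and `ideal` must have equal length", call. = FALSE)
  }
  denom <- sum(ideal^2)
  if (denom == 0) {
    stop("undefined coefficient: `ideal` force is identically zero",
         call. = FALSE)
  }
  sum(measured * ideal) / denom
}

#' Trial inclusion rule
#'
#' Kinematic bounds for retaining a trial: peak speed and reaction time
#' must fall strictly inside their bounds. Defaults exclude extremely slow
#' (< 0.2 m/s) and extremely fast (> 0.55 m/s) movements and reaction times
#' under 75 ms or over 2.5 s.
#'
#' @param speed_bounds Length-2 peak-speed bounds, m/s.
#' @param rt_bounds Length-2 reaction-time bounds, s.
#' @return A list of class `inclusion_rule`.
#' @export
inclusion_rule <- function(speed_bounds = c(0.2, 0.55),
                           rt_bounds = c(0.075, 2.5)) {
  stopifnot(length(speed_bounds) == 2L, speed_bounds[1L] < speed_bounds[2L],
            length(rt_bounds) == 2L, rt_bounds[1L] < rt_bounds[2L])
  structure(list(speed_bounds = speed_bounds, rt_bounds = rt_bounds),
            class = "inclusion_rule")
}

#' Apply the trial inclusion filter
#'
#' Retains trials whose `peak_speed` and `reaction_time` lie strictly
#' inside the rule's bounds. Trials with missing kinematics are excluded
#' and counted separately (never silently dropped from the report).
#'
#' @param trials A trial table with `peak_speed` (m/s) and `reaction_time`
#'   (s) columns.
#' @param rule An [inclusion_rule()].
#' @return The retained trials, with an `exclusion_report` attribute (a
#'   one-row tibble of counts per criterion) retrievable via
#'   [exclusion_report()].
#' @export
apply_inclusion <- function(trials, rule = inclusion_rule()) {
  stopifnot(all(c("peak_speed", "reaction_time") %in% names(trials)))
  sp <- trials$peak_speed; rt <- trials$reaction_time
  missing_kin <- is.na(sp) | is.na(rt)
  bad_speed <- !missing_kin &
    !(sp > rule$speed_bounds[1L] & sp < rule$speed_bounds[2L])
  bad_rt <- !missing_kin &
    !(rt > rule$rt_bounds[1L] & rt < rule$rt_bounds[2L])
  keep <- !missing_kin & !bad_speed & !bad_rt
  report <- tibble::tibble(
    n_total = nrow(trials),
    n_speed_excluded = sum(bad_speed),
    n_rt_excluded = sum(bad_rt),
    n_missing_kinematics = sum(missing_kin),
    n_retained = sum(keep),
    prop_retained = sum(keep) / nrow(trials))
  out <- trials[keep, , drop = FALSE]
  attr(out, "exclusion_report") <- report
  out
}

#' Exclusion report of a filtered trial table
#'
#' @param trials Output of [apply_inclusion()].
#' @return One-row tibble of exclusion counts.
#' @export
exclusion_report <- function(trials) {
  attr(trials, "exclusion_report")
}

#' Generalization pattern from error-clamp trials
#'
#' Per-probe-direction mean and standard error of the adaptation
#' coefficients measured on error-clamp trials.
#'
#' @param clamp_trials A trial table restricted to (or containing)
#'   error-clamp trials, with `target` and `adaptation_at_probe` columns.
#' @return A tibble of class `generalization_pattern` with columns
#'   `direction`, `adaptation` (mean coefficient), `se` (NA when a
#'   direction holds a single trial) and `n`.
#' @export
generalization_pattern <- function(clamp_trials) {
  cl <- dplyr::filter(clamp_trials,
                      !is.na(.data$adaptation_at_probe))
  if ("field_mode" %in% names(cl)) {
    cl <- dplyr::filter(cl, .data$field_mode == "clamp")
  }
  if (nrow(cl) == 0L) stop("no error-clamp trials", call. = FALSE)
  out <- cl |>
    dplyr::group_by(direction = .data$target) |>
    dplyr::summarise(
      adaptation = mean(.data$adaptation_at_probe),
      se = stats::sd(.data$adaptation_at_probe) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$direction)
  if (any(out$n == 1L)) {
    warning("single-trial probe direction(s): standard error undefined",
            call. = FALSE)
  }
  structure(out, class = c("generalization_pattern", class(out)))
}

# wrap-aware dense interpolation of a (direction, value) pattern
interp_pattern <- function(direction, value, step = 0.5) {
  o <- order(direction)
  d <- direction[o]; v <- value[o]
  # pad one wrapped point on each side for circular interpolation
  d_ext <- c(d[length(d)] - 360, d, d[1L] + 360)
  v_ext <- c(v[length(v)], v, v[1L])
  grid <- seq(-180, 180 - step, by = step)
  grid_in <- pmin(pmax(grid, min(d_ext)), max(d_ext))
  tibble::tibble(direction = grid,
                 value = stats::approx(d_ext, v_ext, xout = grid_in)$y)
}

#' Peak-to-trough separation of a bimodal generalization pattern
#'
#' Locates the positive maximum and negative minimum of a pattern on a
#' finely interpolated direction grid (0.5 degrees) and returns the
#' wrap-aware angular distance between them. Both extrema must exceed a
#' noise threshold (default: twice the pattern's pooled standard error,
#' when available) or a no-bimodality error is raised. Ties are broken
#' toward `training_direction` when given.
#'
#' @param pattern A tibble with `direction` and `adaptation` (or `value`)
#'   columns, e.g. a [generalization_pattern()] or
#'   [predicted_generalization()] output.
#' @param noise_threshold Minimum magnitude both extrema must exceed;
#'   `NULL` uses `2 * mean(se)` if the pattern has standard errors, else 0.
#' @param training_direction Optional tie-break direction, degrees.
#' @param step Interpolation step in degrees.
#' @return Separation in degrees, with attributes `peak` and `trough`
#'   (their directions).
#' @export
peak_separation <- function(pattern, noise_threshold = NULL,
                            training_direction = NULL, step = 0.5) {
  value_col <- if ("adaptation" %in% names(pattern)) "adaptation" else "value"
  dense <- interp_pattern(pattern$direction, pattern[[value_col]], step)
  if (is.null(noise_threshold)) {
    noise_threshold <- if ("se" %in% names(pattern) && any(is.finite(pattern$se)))
      2 * mean(pattern$se, na.rm = TRUE) else 0
  }
  vmax <- max(dense$value); vmin <- min(dense$value)
  if (!(vmax > noise_threshold && vmin < -noise_threshold)) {
    stop("no bimodality: pattern lacks a positive peak and negative trough ",
         "beyond the noise threshold", call. = FALSE)
  }
  pick <- function(idx) {
    dirs <- dense$direction[idx]
    if (length(dirs) > 1L && !is.null(training_direction)) {
      dirs[which.min(abs(ang_diff(dirs, training_direction)))]
    } else dirs[1L]
  }
  tol <- 1e-12
  peak <- pick(which(dense$value >= vmax - tol))
  trough <- pick(which(dense$value <= vmin + tol))
  structure(abs(ang_diff(peak, trough)), peak = peak, trough = trough)
}

#' Correlation between two aligned generalization patterns
#'
#' Pearson correlation between predicted and observed pattern values at
#' matching probe directions.
#'
#' @param predicted,observed Tibbles with `direction` and `adaptation` (or
#'   `value`) columns sharing at least 3 probe directions.
#' @return Pearson r.
#' @export
pattern_correlation <- function(predicted, observed) {
  vcol <- function(x) if ("adaptation" %in% names(x)) "adaptation" else "value"
  p <- tibble::tibble(direction = wrap_angle(predicted$direction),
                      p = predicted[[vcol(predicted)]])
  o <- tibble::tibble(direction = wrap_angle(observed$direction),
                      o = observed[[vcol(observed)]])
  m <- dplyr::inner_join(p, o, by = "direction")
  if (nrow(m) < 3L) stop("need at least 3 aligned points", call. = FALSE)
  if (stats::sd(m$p) == 0 || stats::sd(m$o) == 0) {
    stop("undefined correlation: zero-variance pattern", call. = FALSE)
  }
  stats::cor(m$p, m$o)
}

#' Early/late learning-curve summary of an error-clamp series
#'
#' Means of the adaptation coefficients over the first three and last three
#' error-clamp probes, plus the full per-probe curve.
#'
#' @param coefs Adaptation coefficients in trial order (>= 6 values), or a
#'   trial table whose clamp trials supply them.
#' @return A list of class `learning_summary` with `early`, `late` and
#'   `curve` (tibble `probe`, `adaptation`); [generics::glance()] returns
#'   the means as a one-row tibble.
#' @export
learning_summary <- function(coefs) {
  if (is.data.frame(coefs)) {
    coefs <- coefs$adaptation_at_probe[coefs$field_mode == "clamp"]
  }
  coefs <- coefs[!is.na(coefs)]
  if (length(coefs) < 6L) {
    stop("need at least 6 error-clamp probes", call. = FALSE)
  }
  n <- length(coefs)
  structure(list(early = mean(coefs[1:3]),
                 late = mean(coefs[(n - 2):n]),
                 curve = tibble::tibble(probe = seq_len(n),
                                        adaptation = coefs)),
            class = "learning_summary")
}
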