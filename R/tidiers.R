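# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a generalization pattern
#'
#' @param x A [generalization_pattern()].
#' @param ... Unused.
#' @return A tibble with `direction`, `adaptation`, `se`, `n`.
#' @export
tidy.generalization_pattern <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy an adaptation state
#'
#' @param x An [adaptation_state()].
#' @param ... Unused.
#' @return A tibble with `direction` and `value`.
#' @export
tidy.adaptation_state <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy / summarize a learning summary
#'
#' `tidy()` returns the per-probe curve; `glance()` the early and late
#' window means.
#'
#' @param x A [learning_summary()].
#' @param ... Unused.
#' @export
tidy.learning_summary <- function(x, ...) {
  x$curve
}

#' @rdname tidy.learning_summary
#' @export
glance.learning_summary <- function(x, ...) {
  tibble::tibble(early = x$early, late = x$late,
                 n_probes = nrow(x$curve))
}

#' Tidy / summarize an interference-experiment report
#'
#' `tidy()` returns the dense cohort-mean generalization patterns for both
#' hypotheses; `glance()` the scalar summaries (peak separation, mean
#' direction separation, PRL flatness).
#'
#' @param x An `exp1_report` from [run_exp1()].
#' @param ... Unused.
#' @export
tidy.exp1_report <- function(x, ...) {
  x$pattern
}

#' @rdname tidy.exp1_report
#' @export
glance.exp1_report <- function(x, ...) {
  tibble::tibble(peak_separation = x$peak_separation,
                 peak = x$peak, trough = x$trough,
                 error_separation = x$error_separation,
                 prl_flatness = x$prl_flatness,
                 error_gain = x$error_gain,
                 n_subjects = x$n_subjects)
}

#' Tidy / summarize a training-paradigm report
#'
#' `tidy()` returns the mean learning curves; `glance()` the early/late
#' window means per hypothesis and paradigm.
#'
#' @param x An `exp2_report` from [run_exp2()].
#' @param ... Unused.
#' @export
tidy.exp2_report <- function(x, ...) {
  x$curves
}

#' @rdname tidy.exp2_report
#' @export
glance.exp2_report <- function(x, ...) {
  x$summary
}

#' Plot a generalization pattern
#'
#' @param object A [generalization_pattern()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.generalization_pattern <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$direction, y = .data$adaptation)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$adaptation - .data$se,
                   ymax = .data$adaptation + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "movement direction (deg)",
                  y = "adaptation coefficient") +
    ggplot2::theme_minimal()
}

#' Plot an adaptation state
#'
#' @param object An [adaptation_state()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.adaptation_state <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$direction, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "movement direction (deg)",
                  y = "compensation (N/(m/s))") +
    ggplot2::theme_minimal()
}

#' Plot the dense generalization patterns of an interference report
#'
#' @param object An `exp1_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.exp1_report <- function(object, ...) {
  ggplot2::ggplot(object$pattern,
                  ggplot2::aes(x = .data$direction, y = .data$adaptation,
                               colour = .data$hypothesis)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = object$train_dir, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "movement direction (deg)",
                  y = "adaptation coefficient",
                  colour = "learning rule") +
    ggplot2::theme_minimal()
}

#' Plot the learning curves of a training-paradigm report
#'
#' @param object An `exp2_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.exp2_report <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$probe, y = .data$adaptation,
                               colour = .data$paradigm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~hypothesis) +
    ggplot2::labs(x = "error-clamp probe number",
                  y = "adaptation coefficient",
                  colour = "paradigm") +
    ggplot2::theme_minimal()
}
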