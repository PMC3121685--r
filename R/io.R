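# Trial-table serialization (CSV + JSON sidecar) and YAML run
# configuration.

#' Write / read a trial table
#'
#' Writes one row per trial as CSV (list columns such as traces are
#' dropped) together with a JSON sidecar (`<path>.json`) holding the
#' learning parameters, simulation configuration and seed, so a run is
#' reproducible from its files.
#'
#' @param records A trial table from [simulate_experiment()] or
#'   [generate_subject()].
#' @param path CSV file path.
#' @return `write_trial_table()` returns `path` invisibly;
#'   `read_trial_table()` returns the tibble with a `metadata` attribute
#'   when a sidecar is present.
#' @export
write_trial_table <- function(records, path) {
  flat <- records[, !vapply(records, is.list, logical(1)), drop = FALSE]
  readr::write_csv(tibble::as_tibble(flat), path)
  params <- attr(records, "params")
  cfg <- attr(records, "config")
  meta <- list(params = if (!is.null(params)) unclass(params),
               config = if (!is.null(cfg)) unclass(cfg),
               seed = attr(records, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(out, "metadata") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  out
}

#' Read a run configuration from YAML
#'
#' A config names the paradigm and its parameters, e.g.
#' `paradigm: interference`, `train_dir: 270`, `ratio_cw_ccw: [7, 7]`,
#' `seed: 1`, or `paradigm: shifted`, `desired_dir: 90`, `p_ec: 0.2`.
#'
#' @param path YAML file path.
#' @return The parsed configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Build a schedule from a configuration list
#'
#' @param config A list such as [read_run_config()] returns, with a
#'   `paradigm` field of `"interference"` or `"shifted"`; remaining fields
#'   are passed to [interference_schedule()] or [shifted_schedules()].
#' @return A schedule tibble (interference) or the named list of shifted
#'   schedules.
#' @export
schedule_from_config <- function(config) {
  paradigm <- config$paradigm %||% "interference"
  args <- config[setdiff(names(config), "paradigm")]
  if (identical(paradigm, "interference")) {
    do.call(interference_schedule, args)
  } else if (identical(paradigm, "shifted")) {
    do.call(shifted_schedules, args)
  } else {
    stop("unknown paradigm: ", paradigm, call. = FALSE)
  }
}
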