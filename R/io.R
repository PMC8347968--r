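#' Read and write dose histories
#'
#' Dose-history CSVs carry columns `time_min`, `amount_U`, `kind`.
#'
#' @param path File path.
#' @return `read_dose_csv` returns a validated dose-event data frame.
#' @export
read_dose_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  dose_events(d$time_min, d$amount_U, d$kind)
}

#' @rdname read_dose_csv
#' @param doses A dose-event data frame.
#' @export
write_dose_csv <- function(doses, path) {
  validate_dose_events(doses)
  utils::write.csv(doses, path, row.names = FALSE)
  invisible(path)
}

#' Export an activity curve to CSV
#'
#' Columns `bin_start_min`, `fraction`.
#'
#' @param curve An [activity_curve()].
#' @param path File path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(curve_as_data_frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Write simulation outputs as CSV
#'
#' Writes the 1-min plasma-glucose trace, the 5-min CGM trace, the per-bin
#' insulin accounting and the controller trace into `dir`.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_sim_csv <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "sim_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(
    data.frame(time_min = sim$time_min, glucose = sim$glucose),
    file.path(dir, paste0(prefix, "_glucose.csv")), row.names = FALSE
  )
  utils::write.csv(sim$cgm, file.path(dir, paste0(prefix, "_cgm.csv")),
                   row.names = FALSE)
  utils::write.csv(sim$insulin, file.path(dir, paste0(prefix, "_insulin.csv")),
                   row.names = FALSE)
  if (!is.null(sim$trace)) {
    utils::write.csv(sim$trace, file.path(dir, paste0(prefix, "_trace.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read and write patient configuration files
#'
#' Configurations are stored as YAML with the same field names as
#' [patient_config()]; the nested `isf` and `targets` blocks map onto
#' [isf_config()] and [target_range()].
#'
#' @param path File path.
#' @return `read_patient_config` returns a [patient_config()].
#' @export
read_patient_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$isf <- do.call(isf_config, y$isf)
  y$targets <- do.call(target_range, y$targets)
  do.call(patient_config, y)
}

#' @rdname read_patient_config
#' @param config A [patient_config()].
#' @export
write_patient_config <- function(config, path) {
  stopifnot(inherits(config, "patient_config"))
  y <- unclass(config)
  y$isf <- unclass(y$isf)
  y$targets <- unclass(y$targets)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Export an estimate trace to CSV
#'
#' The per-cycle basal estimation columns of a controller trace:
#' `time_min`, `ebasal`, `trend_ebasal`, `ebasal_final`, `isf_used`,
#' `n_used`, `gated`.
#'
#' @param trace A controller trace ([controller_trace()] output) or a
#'   `sim_result`.
#' @param path File path.
#' @param isf_used The predefined ISF used by the estimator (recorded in
#'   the output).
#' @export
write_estimate_csv <- function(trace, path, isf_used = NA) {
  if (inherits(trace, "sim_result")) {
    isf_used <- trace$config$isf$isf_target
    trace <- trace$trace
  }
  out <- data.frame(
    time_min = trace$time_min,
    ebasal = trace$ebasal,
    trend = trace$trend_ebasal,
    ebasal_final = trace$ebasal_final,
    isf_used = isf_used,
    n_used = trace$n_used,
    gated = as.logical(trace$gated)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
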