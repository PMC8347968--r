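#' Dose events
#'
#' A dose history is a data frame with columns `time_min` (minutes since
#' start, >= 0), `amount_U` (units, > 0) and `kind` (`"bolus"` or
#' `"basal_bin"`). Basal insulin delivered continuously is represented as one
#' `basal_bin` event per 5-min bin; both kinds decompose identically through
#' the activity curve.
#'
#' @param time_min Numeric vector of dose times (minutes).
#' @param amount_U Numeric vector of dose amounts (U).
#' @param kind Character vector, `"bolus"` or `"basal_bin"` (recycled).
#' @return A validated data frame of dose events.
#' @export
dose_events <- function(time_min = numeric(0), amount_U = numeric(0),
                        kind = "bolus") {
  d <- data.frame(time_min = as.numeric(time_min),
                  amount_U = as.numeric(amount_U),
                  kind = rep_len(as.character(kind), length(time_min)),
                  stringsAsFactors = FALSE)
  validate_dose_events(d)
  d
}

validate_dose_events <- function(doses) {
  stopifnot(is.data.frame(doses),
            all(c("time_min", "amount_U", "kind") %in% names(doses)))
  if (nrow(doses) == 0) return(invisible(doses))
  if (any(doses$amount_U <= 0)) {
    stop("dose amounts must be > 0", call. = FALSE)
  }
  # negative times are allowed: they denote doses before the reference time
  if (!all(doses$kind %in% c("bolus", "basal_bin"))) {
    stop("dose `kind` must be 'bolus' or 'basal_bin'", call. = FALSE)
  }
  invisible(doses)
}

snap_to_bin <- function(time_min, bin_minutes) {
  round(time_min / bin_minutes) * bin_minutes
}

#' Instantaneous insulin series
#'
#' Per-bin instantaneous insulin (U per bin) starting at `start_time_min`.
#' The decomposition of a single dose through an activity curve yields a
#' series whose values sum to the dosed amount (conservation).
#'
#' @param start_time_min Start time of the first bin (minutes).
#' @param bin_minutes Bin width (minutes).
#' @param values Numeric vector of instantaneous insulin per bin (U/bin).
#' @return An object of class `iseries`.
#' @export
iseries <- function(start_time_min, bin_minutes, values) {
  structure(
    list(start_time_min = start_time_min, bin_minutes = bin_minutes,
         values = as.numeric(values)),
    class = "iseries"
  )
}

#' @export
print.iseries <- function(x, ...) {
  cat(sprintf(
    "<iseries> %d bins of %d min from t = %g min; total %.6f U, peak %.5f U/bin\n",
    length(x$values), as.integer(x$bin_minutes), x$start_time_min,
    sum(x$values), if (length(x$values)) max(x$values) else 0
  ))
  invisible(x)
}

#' Bin start times of an instantaneous series
#' @param x An `iseries`.
#' @return Numeric vector of bin start times in minutes.
#' @export
iseries_times <- function(x) {
  x$start_time_min + (seq_along(x$values) - 1) * x$bin_minutes
}

#' Decompose a dose into instantaneous boluses
#'
#' Spreads a single dose over the activity horizon of `curve`: the bin that
#' starts at the (grid-snapped) dose time receives `amount_U * fractions[1]`,
#' the next bin `amount_U * fractions[2]`, and so on. The series sums to the
#' dosed amount exactly.
#'
#' @param dose A one-row dose-event data frame, or a list with `time_min` and
#'   `amount_U`.
#' @param curve An [activity_curve()].
#' @return An [iseries()] starting at the dose time.
#' @examples
#' curve <- activity_curve(240)
#' s <- decompose_dose(list(time_min = 0, amount_U = 2), curve)
#' sum(s$values)  # 2: conservation
#' @export
decompose_dose <- function(dose, curve) {
  stopifnot(inherits(curve, "activity_curve"))
  amount <- as.numeric(dose$amount_U)
  if (length(amount) != 1L || amount <= 0) {
    stop("`dose` must carry a single positive `amount_U`", call. = FALSE)
  }
  iseries(
    start_time_min = snap_to_bin(as.numeric(dose$time_min), curve$bin_minutes),
    bin_minutes = curve$bin_minutes,
    values = amount * curve$fractions
  )
}

resolve_window <- function(doses, curve, window) {
  bm <- curve$bin_minutes
  if (is.null(window)) {
    if (nrow(doses) == 0) return(c(0, curve$ait_minutes))
    st <- snap_to_bin(doses$time_min, bm)
    c(min(st), max(st) + curve$ait_minutes)
  } else {
    if (length(window) != 2L || window[2] <= window[1]) {
      stop("`window` must be c(start, end) with end > start", call. = FALSE)
    }
    snap_to_bin(window, bm)
  }
}

#' Aggregate instantaneous insulin on board (iIOB)
#'
#' Sums the decompositions of all doses bin by bin over a time window: the
#' instantaneous IOB is the total insulin acting in each bin from all past
#' doses whose activity overlaps it. Additive and homogeneous in the dose
#' amounts.
#'
#' @param doses A dose-event data frame (see [dose_events()]); may be empty.
#' @param curve An [activity_curve()].
#' @param window Optional `c(start_min, end_min)`; defaults to the span of
#'   the doses plus one activity horizon. An empty dose list yields an
#'   all-zero series over the window.
#' @return An [iseries()] of iIOB values (U/bin).
#' @export
aggregate_iiob <- function(doses, curve, window = NULL) {
  stopifnot(inherits(curve, "activity_curve"))
  validate_dose_events(doses)
  bm <- curve$bin_minutes
  win <- resolve_window(doses, curve, window)
  nbins <- as.integer((win[2] - win[1]) / bm)
  values <- numeric(nbins)
  if (nrow(doses) > 0) {
    L <- curve_length(curve)
    for (i in seq_len(nrow(doses))) {
      s0 <- snap_to_bin(doses$time_min[i], bm)
      offset <- as.integer((s0 - win[1]) / bm)  # bin index of dose start
      idx <- seq_len(L) + offset                # target bins, 1-based
      keep <- idx >= 1L & idx <= nbins
      if (any(keep)) {
        values[idx[keep]] <- values[idx[keep]] +
          doses$amount_U[i] * curve$fractions[keep]
      }
    }
  }
  iseries(win[1], bm, values)
}

#' Insulin on board (IOB) net of basal needs
#'
#' IOB at time `t` is the insulin dosed in the past that has yet to act,
#' net of the basal requirement: the sum over all bins from `t` to the last
#' bin in which any dose is still active of `iIOB_n - basal_per_bin`. It may
#' be negative, signalling an insulin deficit relative to basal needs.
#'
#' @param doses A dose-event data frame; may be empty (IOB 0).
#' @param curve An [activity_curve()].
#' @param basal_per_bin Basal needs per bin (U/bin, >= 0) subtracted from
#'   every future active bin.
#' @param t Evaluation time (minutes, snapped to the bin grid).
#' @return IOB in units (scalar).
#' @examples
#' curve <- activity_curve(240)
#' doses <- dose_events(0, 1)
#' compute_iob(doses, curve, basal_per_bin = 0, t = 0)     # 1: all pending
#' compute_iob(doses, curve, basal_per_bin = 0.02, t = 0)  # 1 - 48*0.02
#' @export
compute_iob <- function(doses, curve, basal_per_bin = 0, t = 0) {
  stopifnot(inherits(curve, "activity_curve"))
  validate_dose_events(doses)
  if (basal_per_bin < 0) stop("`basal_per_bin` must be >= 0", call. = FALSE)
  if (nrow(doses) == 0) return(0)
  bm <- curve$bin_minutes
  t <- snap_to_bin(t, bm)
  end_min <- max(snap_to_bin(doses$time_min, bm)) + curve$ait_minutes
  if (end_min <= t) return(0)
  agg <- aggregate_iiob(doses, curve, window = c(t, end_min))
  sum(agg$values - basal_per_bin)
}

#' Signed iIOB error under a misconfigured activity curve
#'
#' Per-bin difference between the iIOB computed with the *configured* curve
#' and with the *true* curve (configured minus true) for the same dose
#' history. Because both curves conserve total insulin, the error integrates
#' to zero over the full horizon: a too-short configured AIT over-estimates
#' early activity (positive error) and under-estimates the tail (negative).
#'
#' @param curve_true True [activity_curve()].
#' @param curve_configured Configured [activity_curve()]; must share
#'   `bin_minutes` with `curve_true`.
#' @param doses Dose-event data frame.
#' @param window Optional `c(start_min, end_min)`; defaults to the union of
#'   both activity horizons over the doses.
#' @return An [iseries()] of signed errors (U/bin).
#' @export
iiob_misconfiguration_error <- function(curve_true, curve_configured, doses,
                                        window = NULL) {
  stopifnot(inherits(curve_true, "activity_curve"),
            inherits(curve_configured, "activity_curve"))
  if (curve_true$bin_minutes != curve_configured$bin_minutes) {
    stop("both curves must share the same `bin_minutes`", call. = FALSE)
  }
  if (is.null(window)) {
    w1 <- resolve_window(doses, curve_true, NULL)
    w2 <- resolve_window(doses, curve_configured, NULL)
    window <- c(min(w1[1], w2[1]), max(w1[2], w2[2]))
  }
  a_cfg <- aggregate_iiob(doses, curve_configured, window)
  a_true <- aggregate_iiob(doses, curve_true, window)
  iseries(a_cfg$start_time_min, a_cfg$bin_minutes,
          a_cfg$values - a_true$values)
}
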