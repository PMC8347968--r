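#' ISF adaptation configuration
#'
#' @param isf_target ISF when glycemia is at target (mg/dL per U, > 0).
#' @param ratio_isf Sensitivity lost per mg/dL of absolute glycemic error
#'   ((mg/dL per U) per mg/dL, >= 0; 0 disables adaptation).
#' @param isf_min Floor for the adapted ISF (mg/dL per U, in (0, isf_target)).
#' @return An object of class `isf_config`.
#' @export
isf_config <- function(isf_target = 50, ratio_isf = 0.1, isf_min = 20) {
  if (!(isf_target > isf_min && isf_min > 0)) {
    stop("need isf_target > isf_min > 0", call. = FALSE)
  }
  if (ratio_isf < 0) stop("`ratio_isf` must be >= 0", call. = FALSE)
  structure(list(isf_target = isf_target, ratio_isf = ratio_isf,
                 isf_min = isf_min), class = "isf_config")
}

#' Glycemic target range
#'
#' @param target_min Lower bound (mg/dL, > 0); also the low-threshold-suspend
#'   glycemia.
#' @param target_max Upper bound (mg/dL, > target_min).
#' @return An object of class `target_range`.
#' @export
target_range <- function(target_min = 100, target_max = 120) {
  if (!(target_min > 0 && target_max > target_min)) {
    stop("need 0 < target_min < target_max", call. = FALSE)
  }
  structure(list(target_min = target_min, target_max = target_max),
            class = "target_range")
}

#' Glycemia-dependent ISF estimate
#'
#' The ISF shrinks linearly with the absolute distance of current glycemia
#' from target: corrections get more aggressive far above target, and more
#' conservative margins apply far below it too.
#'
#' @param sgv_current Current sensor glucose (mg/dL).
#' @param sgv_target Target glucose (mg/dL).
#' @param cfg An [isf_config()].
#' @return Estimated ISF (mg/dL per U), before flooring.
#' @examples
#' estimate_isf(190, 110, isf_config(50, 0.1, 20))  # 42
#' @export
estimate_isf <- function(sgv_current, sgv_target, cfg) {
  cfg$isf_target - cfg$ratio_isf * abs(sgv_current - sgv_target)
}

#' Floor the adapted ISF
#'
#' @param isf_estimated Output of [estimate_isf()].
#' @param cfg An [isf_config()].
#' @return Final ISF, never below `cfg$isf_min`.
#' @export
clamp_isf <- function(isf_estimated, cfg) {
  max(isf_estimated, cfg$isf_min)
}

#' Desired glycemic target
#'
#' Midpoint of the configured target range: the glycemia the controller
#' steers toward while the patient is in range.
#'
#' @param range A [target_range()].
#' @return mg/dL.
#' @export
desired_target <- function(range) {
  (range$target_max + range$target_min) / 2
}

#' Dynamic glycemic target
#'
#' Midpoint between current glycemia and the range floor: when glycemia runs
#' high the working target rises with it, damping over-correction.
#'
#' @param sgv Current sensor glucose (mg/dL).
#' @param range A [target_range()].
#' @return mg/dL (before final clamping).
#' @export
dynamic_target <- function(sgv, range) {
  (sgv + range$target_min) / 2
}

#' Final glycemic target
#'
#' Clamps the dynamic target into `[desired, target_max]`; while the
#' low-threshold-suspend flag is active the target is forced to
#' `target_max`, keeping the loop deliberately unaggressive right after a
#' suspension.
#'
#' @param dynamic Output of [dynamic_target()] (mg/dL).
#' @param desired Output of [desired_target()] (mg/dL).
#' @param range A [target_range()].
#' @param lts_flag Logical low-threshold-suspend flag.
#' @return mg/dL.
#' @export
final_target <- function(dynamic, desired, range, lts_flag) {
  if (isTRUE(lts_flag)) return(range$target_max)
  min(max(dynamic, desired), range$target_max)
}

#' Low-threshold-suspend state
#'
#' @param flag Caution flag (forces the target to `target_max`).
#' @param minutes_since_resume Minutes elapsed since infusion resumed
#'   (`Inf` when no suspension has occurred).
#' @param suspended Whether infusion is currently suspended.
#' @return An object of class `lts_state`.
#' @export
lts_state <- function(flag = FALSE, minutes_since_resume = Inf,
                      suspended = FALSE) {
  structure(list(flag = flag, minutes_since_resume = minutes_since_resume,
                 suspended = suspended), class = "lts_state")
}

#' Update the low-threshold-suspend state
#'
#' Infusion is suspended whenever current *or* eventual glycemia falls below
#' the range floor, independently of any prediction. After resuming, the
#' caution flag stays active for 15 minutes so the loop does not respond
#' abruptly (e.g. to a rebound from carbohydrate intake).
#'
#' @param sgv_current Current sensor glucose (mg/dL).
#' @param sgv_eventual Predicted eventual glucose (mg/dL).
#' @param range A [target_range()]; its `target_min` is the suspend
#'   threshold.
#' @param lts The current [lts_state()].
#' @param step_min Minutes between controller cycles (default 5).
#' @return The updated `lts_state`; `$suspended` is the suspend signal.
#' @export
update_lts <- function(sgv_current, sgv_eventual, range, lts, step_min = 5) {
  low <- range$target_min
  if (sgv_current < low || sgv_eventual < low) {
    lts$suspended <- TRUE
    lts$flag <- TRUE
    lts$minutes_since_resume <- 0
  } else {
    if (lts$suspended) {
      lts$suspended <- FALSE
      lts$minutes_since_resume <- 0
    } else if (is.finite(lts$minutes_since_resume)) {
      lts$minutes_since_resume <- lts$minutes_since_resume + step_min
    }
    lts$flag <- lts$minutes_since_resume < 15
  }
  lts
}
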