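#' Glucose first derivative (dSGV)
#'
#' First difference of consecutive sensor glucose values on the sampling
#' grid, in mg/dL per bin. The instability of glycemia that the basal
#' estimator explains with instantaneous insulin.
#'
#' @param sgv Numeric vector of sensor glucose values (mg/dL), oldest first,
#'   sampled on the 5-min grid.
#' @param all If `TRUE`, return the whole difference series; otherwise
#'   (default) only the most recent pair's difference.
#' @return mg/dL per bin (scalar, or vector when `all = TRUE`).
#' @export
compute_dsgv <- function(sgv, all = FALSE) {
  sgv <- as.numeric(sgv)
  if (length(sgv) < 2) {
    stop(insufficient_data_error("at least 2 CGM samples are needed for dSGV"))
  }
  d <- diff(sgv)
  if (all) d else d[length(d)]
}

insufficient_data_error <- function(msg) {
  errorCondition(msg, class = c("basalloop_insufficient_data", "error"))
}

#' Regression duples
#'
#' A duple pairs the instantaneous insulin on board acting over a sampling
#' bin (`iiob`, U/bin) with the glucose change observed over the same bin
#' (`dsgv`, mg/dL per bin). `valid` flags duples usable for estimation
#' (meal gating clears it).
#'
#' @param time_min Numeric vector of duple times (minutes).
#' @param iiob Instantaneous IOB per bin (U/bin, >= 0).
#' @param dsgv Glucose first difference (mg/dL per bin).
#' @param valid Logical validity flags (default all `TRUE`).
#' @return A data frame with columns `time_min`, `iiob`, `dsgv`, `valid`.
#' @export
regression_duples <- function(time_min, iiob, dsgv, valid = TRUE) {
  if (any(iiob < 0)) stop("`iiob` must be >= 0", call. = FALSE)
  d <- data.frame(time_min = as.numeric(time_min), iiob = as.numeric(iiob),
                  dsgv = as.numeric(dsgv),
                  valid = rep_len(as.logical(valid), length(time_min)))
  if (is.unsorted(d$time_min, strictly = TRUE)) {
    stop("duple times must be strictly increasing", call. = FALSE)
  }
  d
}

valid_duples <- function(duples) {
  if ("valid" %in% names(duples)) duples[duples$valid, , drop = FALSE]
  else duples
}

new_basal_fit <- function(isf, ebasal, method, duples, clamped = FALSE,
                          usable = TRUE, flag = NA_character_) {
  fitted <- -isf * (duples$iiob - ebasal)
  structure(
    list(
      coefficients = c(isf = isf, ebasal = ebasal),
      method = method,
      n = nrow(duples),
      fitted.values = fitted,
      residuals = duples$dsgv - fitted,
      duples = duples,
      clamped = clamped,
      usable = usable,
      flag = flag
    ),
    class = "basal_fit"
  )
}

#' Free least-squares fit of ISF and basal needs
#'
#' Fits the linear law `dsgv = -ISF * (iiob - basal)` to recent duples by
#' ordinary least squares with both parameters free: the ISF is minus the
#' slope of dsgv on iiob, and the basal need is the iIOB at which the fitted
#' line crosses zero (the insulin rate that keeps glycemia flat).
#'
#' A negative fitted ISF (glycemia rising with more active insulin) is
#' physiologically illogical — a known failure mode of small noisy duple
#' sets — and marks the fit unusable. The closed-loop controller therefore
#' relies on [fit_fixed_isf()]; this free fit is diagnostic.
#'
#' @param duples A duple data frame (see [regression_duples()]); rows with
#'   `valid == FALSE` are dropped.
#' @return A `basal_fit` object with `coef()` components `isf` (mg/dL per U)
#'   and `ebasal` (U/bin), plus `usable` / `flag` diagnostics.
#' @examples
#' d <- regression_duples(c(0, 5, 10), iiob = c(0.03, 0.05, 0.07),
#'                        dsgv = c(1, 0, -1))
#' coef(fit_free(d))  # isf 50, ebasal 0.05 recovered exactly
#' @export
fit_free <- function(duples) {
  d <- valid_duples(duples)
  n <- nrow(d)
  if (n < 2) {
    stop(insufficient_data_error("fit_free needs at least 2 valid duples"))
  }
  sxx <- n * sum(d$iiob^2) - sum(d$iiob)^2
  if (sxx <= 0 || isTRUE(all.equal(stats::var(d$iiob), 0))) {
    stop("singular fit: no spread in iIOB across duples", call. = FALSE)
  }
  isf <- -1 * (n * sum(d$dsgv * d$iiob) - sum(d$dsgv) * sum(d$iiob)) / sxx
  usable <- isf > 0
  ebasal <- if (usable) {
    (sum(d$dsgv) + isf * sum(d$iiob)) / (n * isf)
  } else {
    NA_real_
  }
  new_basal_fit(isf, ebasal, "free", d, usable = usable,
                flag = if (usable) NA_character_ else "illogical sensitivity")
}

#' Basal needs with a predefined ISF (fixed-slope regression)
#'
#' Estimates basal needs from duples while the slope of the regression line
#' is pinned at a pre-configured insulin sensitivity factor:
#' `ebasal = (sum(dsgv) + isf * sum(iiob)) / (n * isf)`, which is the exact
#' minimizer of `sum((dsgv + isf * (iiob - b))^2)` over `b`. Fixing the ISF
#' removes the slope's vulnerability to sensor noise, so far fewer duples
#' are needed and the estimator responds faster to changing needs.
#'
#' A negative estimate is clamped to 0 (infusion cannot be negative) and
#' flagged via the `clamped` field.
#'
#' @param duples A duple data frame; rows with `valid == FALSE` are dropped.
#' @param isf_predefined Pre-configured ISF (mg/dL per U, > 0).
#' @return A `basal_fit` object; `coef()["ebasal"]` is the estimate (U/bin).
#' @examples
#' d <- regression_duples(c(0, 5), iiob = c(0.03, 0.07), dsgv = c(1, -1))
#' coef(fit_fixed_isf(d, 50))["ebasal"]  # 0.05 U/bin
#' @export
fit_fixed_isf <- function(duples, isf_predefined) {
  if (!is.numeric(isf_predefined) || isf_predefined <= 0) {
    stop("`isf_predefined` must be > 0", call. = FALSE)
  }
  d <- valid_duples(duples)
  n <- nrow(d)
  if (n < 1) {
    stop(insufficient_data_error("fit_fixed_isf needs at least 1 valid duple"))
  }
  eb <- (sum(d$dsgv) + isf_predefined * sum(d$iiob)) / (n * isf_predefined)
  clamped <- eb < 0
  new_basal_fit(isf_predefined, max(0, eb), "fixed_isf", d, clamped = clamped,
                flag = if (clamped) "clamped at 0" else NA_character_)
}

#' @export
print.basal_fit <- function(x, ...) {
  cat(sprintf("<basal_fit> %s regression on %d duples\n", x$method, x$n))
  cat(sprintf("  ISF %.4g mg/dL per U%s; basal needs %.5g U/bin%s\n",
              x$coefficients[["isf"]],
              if (x$method == "fixed_isf") " (predefined)" else "",
              x$coefficients[["ebasal"]],
              if (isTRUE(x$clamped)) " [clamped]" else ""))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @export
coef.basal_fit <- function(object, ...) object$coefficients

#' @export
residuals.basal_fit <- function(object, ...) object$residuals

#' Predict glucose change from instantaneous insulin
#' @param object A `basal_fit`.
#' @param newdata Optional data frame with an `iiob` column; defaults to the
#'   fitted duples.
#' @param ... Unused.
#' @return Predicted dSGV (mg/dL per bin).
#' @export
predict.basal_fit <- function(object, newdata = NULL, ...) {
  iiob <- if (is.null(newdata)) object$duples$iiob else newdata$iiob
  -object$coefficients[["isf"]] * (iiob - object$coefficients[["ebasal"]])
}

#' @export
summary.basal_fit <- function(object, ...) {
  structure(list(fit = object, rse = sqrt(mean(object$residuals^2))),
            class = "summary.basal_fit")
}

#' @export
print.summary.basal_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  root mean squared residual %.4g mg/dL per bin\n", x$rse))
  invisible(x)
}

#' Detect meals from rapid glucose rises
#'
#' Flags a meal when dSGV exceeds `threshold` for `bins` consecutive duples;
#' the detection time is the time of the last duple in the run.
#'
#' @param duples A duple data frame.
#' @param threshold Detection threshold (mg/dL per bin, default +10).
#' @param bins Consecutive bins required (default 2).
#' @return Numeric vector of detection times (minutes), possibly empty.
#' @export
detect_meals <- function(duples, threshold = 10, bins = 2) {
  hit <- duples$dsgv > threshold
  if (length(hit) < bins) return(numeric(0))
  runs <- stats::filter(as.numeric(hit), rep(1, bins), sides = 1)
  duples$time_min[!is.na(runs) & runs == bins]
}

#' Gate duples around meals
#'
#' Duples falling within `washout_min` after any announced or detected meal
#' are marked invalid: carbohydrate absorption breaks the fasting relation
#' between iIOB and dSGV, so regression results over those periods are
#' discarded and the estimator holds its last finalized estimate.
#'
#' @param duples A duple data frame.
#' @param announced_meals Numeric vector of announced meal times (minutes).
#' @param washout_min Gating window after each meal (minutes, default 180).
#' @param detect Run [detect_meals()] as well (default `TRUE`).
#' @param threshold,bins Passed to [detect_meals()].
#' @return The duple data frame with `valid` updated; detected meal times are
#'   attached as attribute `"detected"`.
#' @export
gate_duples <- function(duples, announced_meals = numeric(0),
                        washout_min = 180, detect = TRUE,
                        threshold = 10, bins = 2) {
  detected <- if (detect) detect_meals(duples, threshold, bins) else numeric(0)
  gates <- c(as.numeric(announced_meals), detected)
  if (length(gates) > 0) {
    bad <- vapply(duples$time_min, function(t) {
      any(t >= gates & t <= gates + washout_min)
    }, logical(1))
    duples$valid <- duples$valid & !bad
  }
  attr(duples, "detected") <- detected
  duples
}

#' Trend of the estimated basal needs
#'
#' Mean of the last three first differences of the basal-needs series
#' (15 min of derivative on the 5-min grid), balancing responsiveness
#' against CGM noise. Histories shorter than 4 points yield 0, the
#' conservative choice.
#'
#' @param ebasal_history Numeric vector of basal estimates (U/bin), oldest
#'   first, on the 5-min grid.
#' @return Trend in U/bin per bin.
#' @examples
#' ebasal_trend(c(0.050, 0.048, 0.046, 0.044))  # -0.002
#' @export
ebasal_trend <- function(ebasal_history) {
  h <- as.numeric(ebasal_history)
  if (length(h) < 4) return(0)
  mean(utils::tail(diff(h), 3))
}

#' Trend-safe finalization of the basal estimate
#'
#' Single-hormone safety rule: a falling trend is extrapolated 15 min ahead
#' (three bins) and subtracted — insulin already dosed cannot be removed, so
#' the controller cuts back early — while a rising trend is ignored, since
#' more insulin can always be added later once the rise is confirmed. The
#' result is clamped at 0.
#'
#' @param ebasal Basal estimate (U/bin).
#' @param trend Trend from [ebasal_trend()] (U/bin per bin).
#' @return Finalized basal needs (U/bin), never above `ebasal`.
#' @examples
#' finalize_ebasal(0.044, -0.002)  # 0.038
#' finalize_ebasal(0.05, 0.01)     # 0.05: rising trend not added
#' @export
finalize_ebasal <- function(ebasal, trend) {
  ebasal <- max(0, ebasal)
  if (trend < 0) max(0, ebasal + trend * 3) else ebasal
}
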