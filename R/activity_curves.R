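#' Insulin activity curve on a fixed bin grid
#'
#' Builds the absorption profile of one unit of rapid-acting insulin over its
#' active insulin time (AIT), discretized into bins aligned with the CGM
#' sampling grid. Each element of `fractions` is the share of the unit that
#' acts (is "absorbed") during that bin, so the curve always sums to exactly 1:
#' dosed insulin is conserved.
#'
#' Two analytic families are available:
#' \describe{
#'   \item{`"exponential"`}{the standard exponential insulin activity model
#'     \eqn{a(t) \propto t\,(1 - t/\mathrm{AIT})\,e^{-t/\tau}}, with
#'     \eqn{\tau} chosen so the activity peaks at `peak_minutes`. It is zero
#'     at \eqn{t = 0} and \eqn{t = \mathrm{AIT}} and unimodal in between.
#'     Requires `peak_minutes < ait_minutes / 2`.}
#'   \item{`"triangular"`}{piecewise-linear rise to `peak_minutes`, then
#'     linear decay to zero at `ait_minutes`.}
#' }
#' Both are evaluated at bin midpoints and renormalized so the fractions sum
#' to 1 within numerical precision.
#'
#' @param ait_minutes Active insulin time (duration of action) in minutes;
#'   must be a positive multiple of `bin_minutes`.
#' @param model_id Curve family, `"exponential"` (default) or `"triangular"`.
#' @param peak_minutes Time of peak activity in minutes, strictly inside the
#'   AIT horizon. Default 75 min, typical of rapid-acting analogues.
#' @param bin_minutes Discretization step in minutes (default 5, the usual
#'   CGM sampling period).
#' @return An object of class `activity_curve`: a list with fields
#'   `ait_minutes`, `bin_minutes`, `fractions`, `model_id`, `peak_minutes`.
#' @examples
#' curve <- activity_curve(240)
#' sum(curve$fractions)  # exactly 1: insulin conservation
#' plot(curve)
#' @export
activity_curve <- function(ait_minutes,
                           model_id = c("exponential", "triangular"),
                           peak_minutes = 75,
                           bin_minutes = 5) {
  model_id <- match.arg(model_id)
  if (!is.numeric(ait_minutes) || length(ait_minutes) != 1L ||
      !is.finite(ait_minutes) || ait_minutes <= 0) {
    stop("`ait_minutes` must be a single positive number of minutes",
         call. = FALSE)
  }
  if (bin_minutes <= 0 || ait_minutes %% bin_minutes != 0) {
    stop("`ait_minutes` must be a positive multiple of `bin_minutes`",
         call. = FALSE)
  }
  if (peak_minutes <= 0 || peak_minutes >= ait_minutes) {
    stop("`peak_minutes` must lie strictly inside (0, ait_minutes)",
         call. = FALSE)
  }
  n <- as.integer(ait_minutes / bin_minutes)
  mid <- (seq_len(n) - 0.5) * bin_minutes

  raw <- switch(model_id,
    exponential = {
      if (peak_minutes >= ait_minutes / 2) {
        stop("the exponential family requires peak_minutes < ait_minutes / 2",
             call. = FALSE)
      }
      tau <- peak_minutes * (1 - peak_minutes / ait_minutes) /
        (1 - 2 * peak_minutes / ait_minutes)
      mid * (1 - mid / ait_minutes) * exp(-mid / tau)
    },
    triangular = ifelse(
      mid <= peak_minutes,
      mid / peak_minutes,
      pmax(0, (ait_minutes - mid) / (ait_minutes - peak_minutes))
    )
  )

  structure(
    list(
      ait_minutes = ait_minutes,
      bin_minutes = bin_minutes,
      fractions = raw / sum(raw),
      model_id = model_id,
      peak_minutes = peak_minutes
    ),
    class = "activity_curve"
  )
}

#' @export
print.activity_curve <- function(x, ...) {
  cat(sprintf(
    "<activity_curve> %s family, AIT %d min, peak ~%d min, %d bins of %d min\n",
    x$model_id, as.integer(x$ait_minutes), as.integer(x$peak_minutes),
    length(x$fractions), as.integer(x$bin_minutes)
  ))
  cat(sprintf("  peak fraction %.4f U/bin per U dosed; sum of fractions %.9f\n",
              max(x$fractions), sum(x$fractions)))
  invisible(x)
}

#' @export
plot.activity_curve <- function(x, ...) {
  t0 <- (seq_along(x$fractions) - 1) * x$bin_minutes
  graphics::plot(t0, x$fractions, type = "h", lwd = 2,
                 xlab = "minutes since dose",
                 ylab = sprintf("activity (U per %d min per U dosed)",
                                as.integer(x$bin_minutes)),
                 main = sprintf("1 U absorption, AIT %d min (%s)",
                                as.integer(x$ait_minutes), x$model_id), ...)
  invisible(x)
}

#' Number of bins in a curve's activity horizon
#' @param curve An `activity_curve`.
#' @return Integer number of bins.
#' @keywords internal
#' @noRd
curve_length <- function(curve) length(curve$fractions)

#' Export an activity curve as a data frame
#'
#' @param curve An `activity_curve`.
#' @return A data frame with columns `bin_start_min` and `fraction`.
#' @export
curve_as_data_frame <- function(curve) {
  stopifnot(inherits(curve, "activity_curve"))
  data.frame(
    bin_start_min = (seq_along(curve$fractions) - 1) * curve$bin_minutes,
    fraction = curve$fractions
  )
}
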