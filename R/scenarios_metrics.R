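#' Default meal schedule
#'
#' The four-meal, 140-g fast-absorption carbohydrate day used by the
#' simulation scenarios: 56 g at 07:00, 37 g at 13:00, 9 g at 17:00 and
#' 38 g at 20:00 (equivalent to a 2000 kcal plan with 28% of calories from
#' carbohydrate, or a 1500 kcal plan with 37%).
#'
#' @return A data frame with columns `time_min`, `grams` and `clock`.
#' @export
default_meal_schedule <- function() {
  data.frame(
    time_min = c(7, 13, 17, 20) * 60,
    grams = c(56, 37, 9, 38),
    clock = c("07:00", "13:00", "17:00", "20:00"),
    stringsAsFactors = FALSE
  )
}

#' Time in glycemic ranges
#'
#' Percentage of samples in the standard bands `<70`, `[70, 180]`, `>180`
#' and `>250` mg/dL, computed on plasma glucose at 1-min resolution (not on
#' the CGM trace). The first three bands partition the samples; `>250` is a
#' subset of `>180`.
#'
#' @param glucose Numeric vector of glucose samples (mg/dL), or a
#'   `sim_result`.
#' @return A named numeric vector with `pct_below_70`, `pct_70_180`,
#'   `pct_above_180`, `pct_above_250`.
#' @export
time_in_range <- function(glucose) {
  if (inherits(glucose, "sim_result")) glucose <- glucose$glucose
  n <- length(glucose)
  if (n == 0) stop("empty glucose trace", call. = FALSE)
  c(
    pct_below_70 = 100 * sum(glucose < 70) / n,
    pct_70_180 = 100 * sum(glucose >= 70 & glucose <= 180) / n,
    pct_above_180 = 100 * sum(glucose > 180) / n,
    pct_above_250 = 100 * sum(glucose > 250) / n
  )
}

#' Total-daily-dose accounting for one simulation
#'
#' Sums the insulin dispensed by the pump (basal plus boluses) over the
#' whole run and on either side of a split clock time, plus the total
#' insulin withheld by any infusion-site blockage. Blocked insulin leaves
#' the reservoir but never absorbs, so it counts toward the TDD while the
#' patient receives `dispensed - blocked`; under a blockage the TDD
#' increment over a matched unblocked run is positive (the controller
#' commands more) yet below the blockage itself, because the patient rides
#' slightly higher glycemia and absorbs a little less insulin overall.
#'
#' @param sim A `sim_result`, or a data frame with columns `time_min`,
#'   `commanded_U`, `bolus_U` and optionally `blocked_U` (per-bin units).
#' @param split_min Split time (minutes, default 720 = 12:00).
#' @return A named numeric vector: `tdd`, `tdd_0_12`, `tdd_after_12`,
#'   `blockage`.
#' @export
tdd_accounting <- function(sim, split_min = 720) {
  ins <- if (inherits(sim, "sim_result")) sim$insulin else sim
  if (!"blocked_U" %in% names(ins)) ins$blocked_U <- 0
  tot <- ins$commanded_U + ins$bolus_U
  pre <- ins$time_min < split_min
  c(
    tdd = sum(tot),
    tdd_0_12 = sum(tot[pre]),
    tdd_after_12 = sum(tot[!pre]),
    blockage = sum(ins$blocked_U)
  )
}

batch_scenario <- function(batch_id) {
  if (!batch_id %in% 1:4) stop("`batch_id` must be 1, 2, 3 or 4",
                               call. = FALSE)
  list(
    meals = if (batch_id %in% c(2, 4)) default_meal_schedule() else NULL,
    blockage = if (batch_id %in% c(3, 4)) {
      blockage_spec(720, mode = "fixed_amount", amount = NULL)
    } else {
      NULL
    }
  )
}

#' Run a simulation batch on a cohort
#'
#' The four scenarios: (1) fasting, (2) four meals, (3) fasting with an
#' infusion blockage from 12:00 equal to half of each patient's
#' predetermined (steady-state) basal, and (4) meals plus blockage. Every
#' cohort member is simulated in closed loop for `duration_min`; per-patient
#' seeds are derived from `seed`, so batches sharing a seed share identical
#' noise and configurations (and identical traces until the scenarios
#' diverge).
#'
#' @param batch_id 1, 2, 3 or 4.
#' @param cohort A [make_cohort()] cohort.
#' @param seed Integer batch seed.
#' @param duration_min Per-patient duration (min, default 1440).
#' @param sensor A [sensor_model()] shared by all patients.
#' @return An object of class `batch_result`: `range_report` (per-group %
#'   time in bands), `tdd_report` (per-patient dose accounting), `tir`
#'   (per-patient bands), `sims` (the individual `sim_result`s), `batch_id`,
#'   `seed`.
#' @export
run_batch <- function(batch_id, cohort, seed = 1, duration_min = 1440,
                      sensor = sensor_model()) {
  stopifnot(inherits(cohort, "vp_cohort"))
  sc <- batch_scenario(batch_id)
  sims <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    sims[[i]] <- simulate_patient(
      cohort[[i]], sensor = sensor, meals = sc$meals,
      blockage = sc$blockage, duration_min = duration_min,
      seed = seed + 101L * i
    )
  }
  groups <- vapply(cohort, function(p) p$group, character(1))
  tir <- t(vapply(sims, time_in_range, numeric(4)))
  tir_df <- data.frame(patient = seq_along(cohort), group = groups, tir)

  range_report <- do.call(rbind, lapply(
    split(as.data.frame(tir), groups),
    function(d) colMeans(d)
  ))
  range_report <- data.frame(group = rownames(range_report), range_report,
                             row.names = NULL)

  tdd <- t(vapply(sims, tdd_accounting, numeric(4)))
  tdd_report <- data.frame(patient = seq_along(cohort), group = groups, tdd)

  structure(
    list(batch_id = batch_id, seed = seed, range_report = range_report,
         tdd_report = tdd_report, tir = tir_df, sims = sims),
    class = "batch_result"
  )
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> batch %d (%s), %d patients, seed %d\n",
              x$batch_id,
              switch(x$batch_id, "fasting", "meals", "blockage",
                     "meals + blockage"),
              nrow(x$tdd_report), x$seed))
  cat("\nPercentage of time in range (plasma glucose):\n")
  r <- x$range_report
  cat(sprintf("  %-12s %8s %10s %8s %8s\n",
              "", "BG<70", "70<BG<180", "BG>180", "BG>250"))
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-12s %7.1f%% %9.1f%% %7.1f%% %7.1f%%\n", r$group[i],
                r$pct_below_70[i], r$pct_70_180[i], r$pct_above_180[i],
                r$pct_above_250[i]))
  }
  cat(sprintf("\nTDD: mean %.2f U (range %.2f-%.2f U)\n",
              mean(x$tdd_report$tdd), min(x$tdd_report$tdd),
              max(x$tdd_report$tdd)))
  invisible(x)
}

#' Per-patient TDD comparison between two batches
#'
#' Pairs the dose accounting of two batches run on the same cohort with the
#' same seed (typically fasting vs. blockage) and reports, per patient, the
#' TDD columns of both, the total insulin blocked, and the TDD increment.
#'
#' @param batch_a,batch_b `batch_result`s on the same cohort and seed.
#' @return A data frame with one row per patient.
#' @export
tdd_comparison <- function(batch_a, batch_b) {
  a <- batch_a$tdd_report
  b <- batch_b$tdd_report
  stopifnot(nrow(a) == nrow(b))
  data.frame(
    patient = a$patient, group = a$group,
    tdd_a = a$tdd, tdd_a_0_12 = a$tdd_0_12, tdd_a_after_12 = a$tdd_after_12,
    tdd_b = b$tdd, tdd_b_0_12 = b$tdd_0_12, tdd_b_after_12 = b$tdd_after_12,
    blockage = b$blockage,
    increment = b$tdd - a$tdd
  )
}
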