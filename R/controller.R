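#' Per-patient controller configuration
#'
#' All tunables of the closed loop for one patient: the insulin activity
#' model, the safety bound on temporary basal, the ISF adaptation settings,
#' the glycemic target range (whose floor doubles as the low-threshold
#' suspend value), the carbohydrate ratio and prebolus policy, the basal
#' history prefill used at start-up, and the estimator's window and meal
#' washout.
#'
#' @param ait_minutes Active insulin time (min, default 240).
#' @param model_id Activity-curve family (see [activity_curve()]).
#' @param peak_minutes Activity peak time (min, default 75).
#' @param max_temp_basal Maximum temporary basal (U/h, > 0).
#' @param isf An [isf_config()].
#' @param targets A [target_range()].
#' @param carb_ratio Grams of carbohydrate per unit of insulin (> 0).
#' @param prebolus_minutes Look-ahead for meal boluses (min, 10-60).
#' @param prebolus_enabled Deliver meal boluses ahead of announced meals.
#' @param initial_basal_prefill Basal history prefill (U/bin) used over one
#'   activity horizon before start; also the fallback command while CGM
#'   history is insufficient.
#' @param window_n Duple window capacity N (default 12, i.e. 1 h).
#' @param washout_min Meal gating washout (min, default 180).
#' @param correction_horizon_min Minutes over which a glycemic error is paid
#'   back through the basal channel (default 60).
#' @param bin_minutes Control/sampling period (min, default 5).
#' @return An object of class `patient_config`.
#' @export
patient_config <- function(ait_minutes = 240,
                           model_id = "exponential",
                           peak_minutes = 75,
                           max_temp_basal = 4,
                           isf = isf_config(),
                           targets = target_range(),
                           carb_ratio = 10,
                           prebolus_minutes = 30,
                           prebolus_enabled = TRUE,
                           initial_basal_prefill = 0.05,
                           window_n = 12,
                           washout_min = 180,
                           correction_horizon_min = 60,
                           bin_minutes = 5) {
  stopifnot(inherits(isf, "isf_config"), inherits(targets, "target_range"))
  if (max_temp_basal <= 0) stop("`max_temp_basal` must be > 0", call. = FALSE)
  if (carb_ratio <= 0) stop("`carb_ratio` must be > 0", call. = FALSE)
  if (initial_basal_prefill < 0) {
    stop("`initial_basal_prefill` must be >= 0", call. = FALSE)
  }
  structure(
    list(ait_minutes = ait_minutes, model_id = model_id,
         peak_minutes = peak_minutes, max_temp_basal = max_temp_basal,
         isf = isf, targets = targets, carb_ratio = carb_ratio,
         prebolus_minutes = prebolus_minutes,
         prebolus_enabled = prebolus_enabled,
         initial_basal_prefill = initial_basal_prefill,
         window_n = window_n, washout_min = washout_min,
         correction_horizon_min = correction_horizon_min,
         bin_minutes = bin_minutes),
    class = "patient_config"
  )
}

#' @export
print.patient_config <- function(x, ...) {
  cat("<patient_config>\n")
  cat(sprintf("  activity: %s, AIT %d min, peak %d min\n",
              x$model_id, as.integer(x$ait_minutes),
              as.integer(x$peak_minutes)))
  cat(sprintf("  ISF %g mg/dL/U (ratio %g, min %g); target [%g, %g] mg/dL\n",
              x$isf$isf_target, x$isf$ratio_isf, x$isf$isf_min,
              x$targets$target_min, x$targets$target_max))
  cat(sprintf("  carb ratio %g g/U, prebolus %d min (%s)\n",
              x$carb_ratio, as.integer(x$prebolus_minutes),
              if (x$prebolus_enabled) "enabled" else "disabled"))
  cat(sprintf("  max temp basal %g U/h, prefill %.4g U/bin, N = %d, washout %d min\n",
              x$max_temp_basal, x$initial_basal_prefill,
              as.integer(x$window_n), as.integer(x$washout_min)))
  invisible(x)
}

#' Initialize controller state
#'
#' Builds the mutable per-patient controller state: the activity curve and
#' its tail sums, empty CGM/duple/estimate histories, and a basal dose
#' history prefilled with `initial_basal_prefill` over one full activity
#' horizon, so iIOB is defined from the very first cycle.
#'
#' The state is an environment (reference semantics): [controller_step()]
#' updates it in place and also returns it.
#'
#' @param config A [patient_config()].
#' @return An object of class `controller_state` (an environment).
#' @export
controller_init <- function(config) {
  stopifnot(inherits(config, "patient_config"))
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$curve <- activity_curve(config$ait_minutes, config$model_id,
                             config$peak_minutes, config$bin_minutes)
  st$L <- length(st$curve$fractions)
  st$frac <- st$curve$fractions
  tails <- rev(cumsum(rev(st$frac)))          # tails[j] = sum(frac[j:L])
  st$tail_rem <- c(tails[-1], 0)              # remaining activity at age a
  cap <- st$L + 512L
  st$basal_bins <- numeric(cap)
  st$bolus_bins <- numeric(cap)
  st$basal_bins[seq_len(st$L)] <- config$initial_basal_prefill  # bins -L..-1
  st$ncgm <- 0L
  st$cgm <- numeric(512)
  st$cgm_time <- numeric(512)
  st$dsgv <- numeric(512)
  st$nd <- 0L
  st$dup_time <- numeric(512)
  st$dup_iiob <- numeric(512)
  st$dup_dsgv <- numeric(512)
  st$dup_valid <- logical(512)
  st$neb <- 0L
  st$ebasal_hist <- numeric(512)
  st$lts <- lts_state()
  st$last_ebasal <- config$initial_basal_prefill
  st$last_final <- config$initial_basal_prefill
  st$detect_gate_until <- -Inf
  st$meal_dosed <- character(0)
  st$trace <- vector("list", 512)
  st$ntrace <- 0L
  class(st) <- c("controller_state", "environment")
  st
}

grow_state <- function(st, need) {
  cap <- length(st$basal_bins)
  if (need <= cap) return(invisible(st))
  newcap <- max(need, 2L * cap)
  for (f in c("basal_bins", "bolus_bins")) {
    v <- st[[f]]
    length(v) <- newcap
    v[is.na(v)] <- 0
    st[[f]] <- v
  }
  invisible(st)
}

grow_vec <- function(st, field, need, fill = 0) {
  v <- st[[field]]
  if (need > length(v)) {
    old <- length(v)
    length(v) <- max(need, 2L * old)
    if (is.numeric(fill)) v[is.na(v)] <- fill
    st[[field]] <- v
  }
  invisible(st)
}

#' Eventual glycemia
#'
#' Short-horizon prediction used for corrections and the suspend decision:
#' the current reading plus a 15-min linear extrapolation of the CGM trend,
#' minus the glycemic drop that pending insulin (IOB) will still cause at
#' the current ISF.
#'
#' @param sgv Current sensor glucose (mg/dL).
#' @param trend_sgv CGM trend (mg/dL per bin, 15-min averaged).
#' @param iob Insulin on board net of basal needs (U).
#' @param isf_final Final ISF (mg/dL per U).
#' @return Predicted glucose (mg/dL).
#' @examples
#' eventual_glycemia(180, 5, 1, 50)  # 180 + 15 - 50 = 145
#' @export
eventual_glycemia <- function(sgv, trend_sgv, iob, isf_final) {
  sgv + 3 * trend_sgv - iob * isf_final
}

#' Correction insulin rate
#'
#' Insulin added to (or subtracted from) the basal needs to pay back the
#' glycemic error over `horizon_min`: `error / ISF` units spread over the
#' horizon's bins. Negative when glucose sits below target.
#'
#' @param eventual Eventual glycemia (mg/dL).
#' @param target_final Final glycemic target (mg/dL).
#' @param isf_final Final ISF (mg/dL per U).
#' @param horizon_min Payback horizon (min, default 60).
#' @param bin_minutes Bin width (min, default 5).
#' @return Correction rate (U/bin), signed.
#' @examples
#' correction_insulin(170, 110, 50, 60)  # (60/50)/12 = 0.1 U/bin
#' @export
correction_insulin <- function(eventual, target_final, isf_final,
                               horizon_min = 60, bin_minutes = 5) {
  ((eventual - target_final) / isf_final) / (horizon_min / bin_minutes)
}

#' Meal bolus
#'
#' @param grams Announced carbohydrates (g, >= 0).
#' @param carb_ratio Grams covered by one unit (g/U, > 0).
#' @return Bolus size (U).
#' @examples
#' meal_bolus(56, 8)  # 7
#' @export
meal_bolus <- function(grams, carb_ratio) {
  if (carb_ratio <= 0) stop("`carb_ratio` must be > 0", call. = FALSE)
  if (grams < 0) stop("`grams` must be >= 0", call. = FALSE)
  grams / carb_ratio
}

#' One closed-loop controller cycle
#'
#' Executes the per-cycle algorithm: store the CGM sample and its first
#' difference; compute iIOB for basal and bolus insulin separately and the
#' IOB net of the current basal-needs estimate; adapt the ISF to current
#' glycemia; predict eventual glycemia; update the low-threshold-suspend
#' state; derive the dynamic and final glycemic targets; append the
#' (iIOB, dSGV) duple with meal gating and re-estimate basal needs with the
#' fixed-slope regression plus trend-safe finalization; add the correction
#' insulin; clamp the commanded basal to `[0, max_temp_basal]` (zero while
#' suspended); deliver at most one prebolus per announced meal; and record
#' everything in the trace.
#'
#' While fewer than two CGM samples are available the controller falls back
#' to commanding the configured prefill with no bolus, flagged in the trace.
#'
#' @param state A [controller_init()] state (updated in place).
#' @param sgv Current sensor glucose sample (mg/dL).
#' @param time_min Sample time (minutes, on the bin grid).
#' @param announced_meals Optional data frame with columns `time_min` and
#'   `grams` (the full announced schedule may be passed every cycle).
#' @return A list with `action` (fields `basal_rate` in U/min, `bolus_U`,
#'   `suspended`, `gated`, `insufficient`) and `state`.
#' @export
controller_step <- function(state, sgv, time_min, announced_meals = NULL) {
  cfg <- state$config
  bm <- cfg$bin_minutes
  L <- state$L
  bin <- as.integer(round(time_min / bm))
  idx <- bin + L + 1L
  grow_state(state, idx + 1L)

  # -- store CGM and dSGV ----------------------------------------------------
  n <- state$ncgm + 1L
  grow_vec(state, "cgm", n); grow_vec(state, "cgm_time", n)
  grow_vec(state, "dsgv", n)
  state$ncgm <- n
  state$cgm[n] <- sgv
  state$cgm_time[n] <- time_min
  insufficient <- n < 2L
  dsgv <- if (insufficient) NA_real_ else sgv - state$cgm[n - 1L]
  state$dsgv[n] <- if (insufficient) 0 else dsgv

  # -- instantaneous and pending insulin from delivered history -------------
  ages <- idx - seq_len(L)                # storage rows of bins t-1 .. t-L
  basal_rev <- state$basal_bins[ages]
  bolus_rev <- state$bolus_bins[ages]
  iiob_basal <- sum(basal_rev * state$frac)
  iiob_bolus <- sum(bolus_rev * state$frac)
  iiob_total <- iiob_basal + iiob_bolus
  # surplus IOB: past deviations from basal needs, weighted by the share of
  # their activity still to come (0 at steady delivery; ~ bolus size right
  # after a bolus; negative after a suspension)
  iob <- sum((basal_rev + bolus_rev - state$last_final) * state$tail_rem)

  # -- adaptive ISF ----------------------------------------------------------
  des <- desired_target(cfg$targets)
  isf_final <- clamp_isf(estimate_isf(sgv, des, cfg$isf), cfg$isf)

  # -- eventual glycemia and LTS --------------------------------------------
  k <- min(3L, n - 1L)
  trend_sgv <- if (k >= 3L) mean(state$dsgv[(n - k + 1L):n]) else 0
  eventual <- eventual_glycemia(sgv, trend_sgv, iob, isf_final)
  state$lts <- update_lts(sgv, eventual, cfg$targets, state$lts, bm)
  suspended <- state$lts$suspended

  # -- glycemic targets ------------------------------------------------------
  dyn <- dynamic_target(sgv, cfg$targets)
  tfinal <- final_target(dyn, des, cfg$targets, state$lts$flag)

  meal_times <- if (!is.null(announced_meals) && nrow(announced_meals)) {
    announced_meals$time_min
  } else {
    numeric(0)
  }

  gated <- FALSE
  n_used <- 0L
  ebasal <- state$last_ebasal
  if (!insufficient) {
    # -- duple, gating, estimation ------------------------------------------
    if (n >= 3L && state$dsgv[n] > 10 && state$dsgv[n - 1L] > 10) {
      state$detect_gate_until <- time_min + cfg$washout_min
    }
    gated <- any(time_min >= meal_times &
                   time_min <= meal_times + cfg$washout_min) ||
      time_min <= state$detect_gate_until

    m <- state$nd + 1L
    grow_vec(state, "dup_time", m); grow_vec(state, "dup_iiob", m)
    grow_vec(state, "dup_dsgv", m); grow_vec(state, "dup_valid", m, fill = NA)
    state$nd <- m
    state$dup_time[m] <- time_min
    state$dup_iiob[m] <- iiob_total
    state$dup_dsgv[m] <- dsgv
    state$dup_valid[m] <- !gated

    win <- max(1L, m - cfg$window_n + 1L):m
    use <- win[state$dup_valid[win]]
    n_used <- length(use)
    if (length(use) >= 1L) {
      d <- regression_duples(state$dup_time[use], state$dup_iiob[use],
                             state$dup_dsgv[use])
      fit <- fit_fixed_isf(d, cfg$isf$isf_target)
      ebasal <- coef(fit)[["ebasal"]]
    }  # else: hold the last estimate while gated
  }
  ne <- state$neb + 1L
  grow_vec(state, "ebasal_hist", ne)
  state$neb <- ne
  state$ebasal_hist[ne] <- ebasal
  state$last_ebasal <- ebasal
  trend_eb <- ebasal_trend(state$ebasal_hist[max(1L, ne - 3L):ne])
  eb_final <- finalize_ebasal(ebasal, trend_eb)
  state$last_final <- eb_final

  # -- commanded basal -------------------------------------------------------
  corr <- correction_insulin(eventual, tfinal, isf_final,
                             cfg$correction_horizon_min, bm)
  max_bin <- cfg$max_temp_basal * bm / 60
  commanded <- if (insufficient) {
    min(cfg$initial_basal_prefill, max_bin)
  } else {
    min(max(eb_final + corr, 0), max_bin)
  }
  if (suspended) commanded <- 0

  # -- prebolus for announced meals -----------------------------------------
  bolus <- 0
  if (!insufficient && !suspended && cfg$prebolus_enabled &&
      length(meal_times)) {
    lead <- meal_times - time_min
    due <- which(lead >= 0 & lead <= cfg$prebolus_minutes &
                   !(as.character(meal_times) %in% state$meal_dosed))
    if (length(due)) {
      bolus <- sum(meal_bolus(announced_meals$grams[due], cfg$carb_ratio))
      state$meal_dosed <- c(state$meal_dosed,
                            as.character(meal_times[due]))
    }
  }

  # -- record action in dose history ----------------------------------------
  state$basal_bins[idx] <- commanded
  state$bolus_bins[idx] <- bolus

  nt <- state$ntrace + 1L
  if (nt > length(state$trace)) {
    length(state$trace) <- 2L * length(state$trace)
  }
  state$ntrace <- nt
  state$trace[[nt]] <- c(
    time_min = time_min, sgv = sgv,
    dsgv = if (insufficient) NA_real_ else dsgv,
    iiob = iiob_total, iiob_basal = iiob_basal, iiob_bolus = iiob_bolus,
    iob = iob, eventual = eventual, target_dynamic = dyn,
    target_final = tfinal, isf_final = isf_final, ebasal = ebasal,
    trend_ebasal = trend_eb, ebasal_final = eb_final, n_used = n_used,
    correction = corr,
    commanded_basal = commanded, bolus = bolus,
    lts_flag = as.numeric(state$lts$flag), suspended = as.numeric(suspended),
    gated = as.numeric(gated), insufficient = as.numeric(insufficient)
  )

  list(
    action = list(basal_rate = commanded / bm, bolus_U = bolus,
                  suspended = suspended, gated = gated,
                  insufficient = insufficient),
    state = state
  )
}

#' Controller trace as a data frame
#'
#' @param state A `controller_state` after one or more steps.
#' @return One row per cycle with the per-cycle quantities (glucose, iIOB,
#'   IOB, targets, ISF, basal estimates, correction, commanded insulin and
#'   flags).
#' @export
controller_trace <- function(state) {
  rows <- state$trace[seq_len(state$ntrace)]
  as.data.frame(do.call(rbind, rows))
}

#' @export
print.controller_state <- function(x, ...) {
  cat(sprintf(
    "<controller_state> %d cycles; last basal estimate %.4g U/bin (final %.4g)\n",
    x$ntrace, x$last_ebasal, x$last_final))
  invisible(x)
}
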