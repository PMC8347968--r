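#' Virtual patient parameters
#'
#' A Bergman-type minimal model of glucose-insulin physiology with a
#' one-compartment gut for meals:
#' \deqn{dG/dt = -p_1 G - X G + P_0 + f k_a Q / V_g}
#' \deqn{dX/dt = -p_2 X + p_3 I_p}
#' \deqn{dI_p/dt = -k_e I_p + u(t) / V_i}
#' \deqn{dQ/dt = -k_a Q + \textrm{meals}}
#' where `G` is plasma glucose (mg/dL), `X` remote insulin action (1/min),
#' `Ip` plasma insulin (U/L), `Q` gut carbohydrate (mg), and `u` the insulin
#' infusion (U/min). `P0` is the net endogenous glucose production,
#' constructed so that glucose is in steady state at `Gb` under the basal
#' infusion implied by the other parameters; with no insulin, glucose drifts
#' up toward `P0 / p1`.
#'
#' The model admits a closed-form steady state, which makes the patient's
#' true basal requirement (see [steady_state_basal()]) and an approximate
#' insulin sensitivity factor available analytically — the properties that
#' make controller validation tractable.
#'
#' @param group Cohort group label: `"adult"`, `"adolescent"` or `"child"`.
#' @param Gb Basal (fasting steady-state) glucose under basal insulin
#'   (mg/dL).
#' @param p1 Insulin-independent glucose effectiveness (1/min).
#' @param p2 Remote insulin action decay rate (1/min).
#' @param p3 Insulin action gain ((U/L)^-1 min^-2).
#' @param ke Plasma insulin clearance rate (1/min).
#' @param Vi Insulin distribution volume (L).
#' @param Vg_dL Glucose distribution volume (dL).
#' @param ka Gut absorption rate (1/min).
#' @param f_carb Carbohydrate bioavailability (0-1).
#' @param X_ss Steady-state remote insulin action (1/min); together with
#'   `Gb` it fixes `P0 = (p1 + X_ss) * Gb`.
#' @return An object of class `vp_params`.
#' @export
vp_params <- function(group = c("adult", "adolescent", "child"),
                      Gb = 130, p1 = 0.008, p2 = 0.012, p3 = 0.0017,
                      ke = 0.025, Vi = 8, Vg_dL = 160, ka = 0.02,
                      f_carb = 0.8, X_ss = 0.012) {
  group <- match.arg(group)
  vals <- c(Gb = Gb, p1 = p1, p2 = p2, p3 = p3, ke = ke, Vi = Vi,
            Vg_dL = Vg_dL, ka = ka, f_carb = f_carb, X_ss = X_ss)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all virtual-patient parameters must be positive and finite",
         call. = FALSE)
  }
  if (f_carb > 1) stop("`f_carb` must be <= 1", call. = FALSE)
  structure(
    list(group = group, Gb = Gb, p1 = p1, p2 = p2, p3 = p3, ke = ke,
         Vi = Vi, Vg_dL = Vg_dL, ka = ka, f_carb = f_carb, X_ss = X_ss,
         P0 = (p1 + X_ss) * Gb),
    class = "vp_params"
  )
}

#' @export
print.vp_params <- function(x, ...) {
  cat(sprintf("<vp_params> %s: Gb %.0f mg/dL, steady basal %.3f U/h, ISF ~%.0f mg/dL/U\n",
              x$group, x$Gb, steady_state_basal(x) * 60, patient_isf(x)))
  invisible(x)
}

#' True steady-state basal requirement
#'
#' Closed-form infusion rate that holds plasma glucose at `Gb` with no
#' meals: at equilibrium `X = X_ss = P0/Gb - p1`, which requires
#' `Ip = X_ss * p2 / p3` and hence `u = ke * Vi * Ip`. Strictly decreasing
#' in the insulin action gain `p3`: a more sensitive patient needs less
#' basal insulin.
#'
#' @param params A [vp_params()].
#' @return Basal infusion in U/min.
#' @export
steady_state_basal <- function(params) {
  stopifnot(inherits(params, "vp_params"))
  X_ss <- params$P0 / params$Gb - params$p1
  if (X_ss <= 0) {
    stop("degenerate parameters: no positive-insulin steady state exists",
         call. = FALSE)
  }
  params$ke * params$Vi * X_ss * params$p2 / params$p3
}

#' Approximate insulin sensitivity factor of a virtual patient
#'
#' Total glycemic drop per unit of insulin, from the integrated insulin
#' action of a 1-U bolus at glucose `G`: `G * p3 / (p2 * ke * Vi)`. Used to
#' derive a consistent controller configuration; the realized drop is
#' somewhat smaller because glucose effectiveness (`p1`) pulls glycemia
#' back while insulin acts.
#'
#' @param params A [vp_params()].
#' @param G Reference glucose (mg/dL, default 110).
#' @return ISF in mg/dL per U.
#' @export
patient_isf <- function(params, G = 110) {
  G * params$p3 / (params$p2 * params$ke * params$Vi)
}

#' CGM sensor model
#'
#' Interstitial sensing is modelled as a pure delay on plasma glucose plus
#' first-order autoregressive noise: `e_t = rho * e_{t-1} +
#' sqrt(1 - rho^2) * sd * z_t` at each 5-min sample, so the marginal noise
#' standard deviation is `noise_sd`.
#'
#' @param delay_min Sensing delay (min, within 10-20).
#' @param noise_sd Marginal noise standard deviation (mg/dL, >= 0; 0 gives a
#'   noiseless sensor).
#' @param rho AR(1) autocorrelation of consecutive samples (in [0, 1)).
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(delay_min = 10, noise_sd = 3, rho = 0.7) {
  if (delay_min < 10 || delay_min > 20) {
    stop("`delay_min` must lie in [10, 20] minutes", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("`rho` must be in [0, 1)", call. = FALSE)
  structure(list(delay_min = delay_min, noise_sd = noise_sd, rho = rho),
            class = "sensor_model")
}

#' Infusion blockage specification
#'
#' Insulin commanded by the controller but withheld from delivery, starting
#' at `start_time_min`. In `fixed_amount` mode the blocked insulin per bin
#' is a fixed quantity (the experimental protocol blocks half of the
#' patient's predetermined basal needs); in `fractional` mode a fraction of
#' every command is withheld.
#'
#' @param start_time_min Blockage onset (minutes).
#' @param mode `"fixed_amount"` or `"fractional"`.
#' @param amount Blocked U/bin (`fixed_amount`) or fraction in [0, 1]
#'   (`fractional`). For `fixed_amount`, `NULL` means half of the
#'   predetermined basal supplied to [apply_blockage()].
#' @return An object of class `blockage_spec`.
#' @export
blockage_spec <- function(start_time_min, mode = c("fixed_amount", "fractional"),
                          amount = NULL) {
  mode <- match.arg(mode)
  if (!is.null(amount) && amount < 0) {
    stop("`amount` must be >= 0", call. = FALSE)
  }
  if (mode == "fractional" &&
      (is.null(amount) || amount > 1)) {
    stop("fractional mode needs `amount` in [0, 1]", call. = FALSE)
  }
  structure(list(start_time_min = start_time_min, mode = mode,
                 amount = amount),
            class = "blockage_spec")
}

#' Apply an infusion blockage to commanded basal insulin
#'
#' @param commanded Numeric vector of commanded basal insulin per bin
#'   (U/bin).
#' @param times Bin start times (minutes), same length as `commanded`.
#' @param spec A [blockage_spec()], or `NULL` for no blockage.
#' @param predetermined_basal The patient's predetermined basal needs
#'   (U/bin), used when a `fixed_amount` spec has no explicit amount
#'   (half of it is then blocked, the experimental protocol).
#' @return A list with vectors `delivered` and `blocked`
#'   (`delivered = commanded - blocked`, elementwise >= 0).
#' @export
apply_blockage <- function(commanded, times, spec,
                           predetermined_basal = NULL) {
  if (is.null(spec)) {
    return(list(delivered = commanded, blocked = numeric(length(commanded))))
  }
  stopifnot(inherits(spec, "blockage_spec"),
            length(times) == length(commanded))
  active <- times >= spec$start_time_min
  delivered <- commanded
  if (spec$mode == "fixed_amount") {
    amt <- spec$amount
    if (is.null(amt)) {
      if (is.null(predetermined_basal)) {
        stop("fixed_amount blockage needs `amount` or `predetermined_basal`",
             call. = FALSE)
      }
      amt <- 0.5 * predetermined_basal
    }
    delivered[active] <- pmax(0, commanded[active] - amt)
  } else {
    delivered[active] <- (1 - spec$amount) * commanded[active]
  }
  list(delivered = delivered, blocked = commanded - delivered)
}

#' Generate a synthetic virtual-patient cohort
#'
#' Seeded draws from group-specific parameter ranges. Groups differ mainly
#' in size-related quantities: children have smaller distribution volumes,
#' lower basal requirements (roughly a third of adults') and higher insulin
#' sensitivity, matching the qualitative ordering of real pediatric/adult
#' insulin needs.
#'
#' @param n_adult,n_adolescent,n_child Group sizes.
#' @param seed Integer seed; the cohort is reproducible.
#' @return An object of class `vp_cohort`: a list of [vp_params()].
#' @export
make_cohort <- function(n_adult = 10, n_adolescent = 10, n_child = 10,
                        seed = 1) {
  draw <- function(group, n) {
    if (n == 0) return(list())
    rng <- switch(group,
      adult = list(basal_Uh = c(0.80, 1.30), Vg = c(140, 190),
                   Vi = c(7, 10)),
      adolescent = list(basal_Uh = c(0.55, 0.95), Vg = c(100, 140),
                        Vi = c(5, 8)),
      child = list(basal_Uh = c(0.25, 0.45), Vg = c(55, 85),
                   Vi = c(3, 5))
    )
    lapply(seq_len(n), function(i) {
      u_ss <- stats::runif(1, rng$basal_Uh[1], rng$basal_Uh[2]) / 60  # U/min
      Gb <- stats::runif(1, 115, 145)
      p1 <- stats::runif(1, 0.006, 0.010)
      p2 <- stats::runif(1, 0.010, 0.016)
      ke <- stats::runif(1, 0.020, 0.035)
      Vi <- stats::runif(1, rng$Vi[1], rng$Vi[2])
      X_ss <- stats::runif(1, 1.2, 1.8) * p1
      Ip_ss <- u_ss / (ke * Vi)
      p3 <- p2 * X_ss / Ip_ss
      vp_params(group, Gb = Gb, p1 = p1, p2 = p2, p3 = p3, ke = ke,
                Vi = Vi, Vg_dL = stats::runif(1, rng$Vg[1], rng$Vg[2]),
                ka = stats::runif(1, 0.015, 0.025),
                f_carb = stats::runif(1, 0.75, 0.9), X_ss = X_ss)
    })
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  cohort <- c(draw("adult", n_adult), draw("adolescent", n_adolescent),
              draw("child", n_child))
  structure(cohort, class = "vp_cohort", seed = seed)
}

#' @export
print.vp_cohort <- function(x, ...) {
  groups <- vapply(x, function(p) p$group, character(1))
  cat(sprintf("<vp_cohort> %d patients (%s)\n", length(x),
              paste(sprintf("%d %s", table(groups), names(table(groups))),
                    collapse = ", ")))
  invisible(x)
}

#' Derive a consistent controller configuration for a virtual patient
#'
#' Sets the configured ISF from the patient's analytic sensitivity, the
#' carbohydrate ratio from the carb-to-glucose balance
#' `CR = ISF * Vg / (1000 * f)`, the maximum temporary basal at four times
#' the steady-state basal (at least 2 U/h), and the basal-history prefill
#' at the true steady-state basal jittered by up to +/-20% (each patient
#' starts from a merely approximate prior, as in practice). The prebolus
#' lead time is drawn uniformly in 10-60 min.
#'
#' @param params A [vp_params()].
#' @param seed Integer seed for the prefill jitter and prebolus draw.
#' @param ... Overrides passed on to [patient_config()].
#' @return A [patient_config()].
#' @export
config_for_patient <- function(params, seed = 1, ...) {
  stopifnot(inherits(params, "vp_params"))
  u_bin <- steady_state_basal(params) * 5          # U per 5-min bin
  isf <- patient_isf(params)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  jitter <- stats::runif(1, -0.2, 0.2)
  prebolus <- round(stats::runif(1, 10, 60))
  defaults <- list(
    max_temp_basal = max(2, 4 * steady_state_basal(params) * 60),
    isf = isf_config(isf_target = isf, ratio_isf = isf / 500,
                     isf_min = isf / 2.5),
    carb_ratio = isf * params$Vg_dL / (1000 * params$f_carb),
    prebolus_minutes = prebolus,
    initial_basal_prefill = u_bin * (1 + jitter)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(patient_config, args)
}

#' Simulate a virtual patient in closed loop
#'
#' Integrates the minimal-model physiology at 1-min substeps (forward
#' Euler) for `duration_min` minutes. Every 5 min the controller receives a
#' delayed, noisy CGM sample and commands a basal rate (and possibly a
#' bolus); any blockage is applied to the commanded basal before delivery.
#' Deterministic given `seed`.
#'
#' @param params A [vp_params()].
#' @param config A [patient_config()]; `NULL` derives one with
#'   [config_for_patient()] using `seed`.
#' @param sensor A [sensor_model()].
#' @param meals Optional meal schedule data frame with `time_min`, `grams`
#'   (announced to the controller).
#' @param blockage Optional [blockage_spec()]; a `fixed_amount` spec without
#'   an explicit amount blocks half of the patient's steady-state basal.
#' @param duration_min Simulation length (min, multiple of 5; default
#'   1440 = 24 h).
#' @param seed Integer seed for sensor noise (and the derived config).
#' @param open_loop_basal If non-`NULL`, bypass the controller and infuse
#'   this constant basal rate (U/min) with no boluses.
#' @return An object of class `sim_result`: 1-min `time_min`, `glucose` and
#'   carb absorption `ra` (mg/dL per min), the 5-min `cgm` data frame, per-bin `insulin` accounting (`commanded_U`,
#'   `delivered_U`, `blocked_U`, `bolus_U`), the controller `trace`, plus
#'   `meals`, `params`, `config`, `seed`.
#' @export
simulate_patient <- function(params, config = NULL, sensor = sensor_model(),
                             meals = NULL, blockage = NULL,
                             duration_min = 1440, seed = 1,
                             open_loop_basal = NULL) {
  stopifnot(inherits(params, "vp_params"), inherits(sensor, "sensor_model"))
  if (duration_min %% 5 != 0 || duration_min <= 0) {
    stop("`duration_min` must be a positive multiple of 5", call. = FALSE)
  }
  if (is.null(config)) config <- config_for_patient(params, seed = seed)

  u_ss <- steady_state_basal(params)           # U/min
  block_amt <- NULL
  if (!is.null(blockage) && blockage$mode == "fixed_amount" &&
      is.null(blockage$amount)) {
    block_amt <- 0.5 * u_ss * 5                # U/bin
  } else if (!is.null(blockage)) {
    block_amt <- blockage$amount
  }

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  nmin <- duration_min
  nbins <- nmin %/% 5L
  G <- numeric(nmin + 1L)
  # initial state: patient at basal steady state
  g <- params$Gb
  x <- params$P0 / params$Gb - params$p1
  ip <- x * params$p2 / params$p3
  q <- 0
  G[1L] <- g

  ra_vec <- numeric(nmin)                      # absorbed carbs, mg/dL per min
  cgm_t <- numeric(nbins); cgm_v <- numeric(nbins)
  commanded_U <- numeric(nbins); delivered_U <- numeric(nbins)
  blocked_U <- numeric(nbins); bolus_U <- numeric(nbins)

  ctrl <- if (is.null(open_loop_basal)) controller_init(config) else NULL
  noise <- 0
  meal_t <- if (!is.null(meals)) meals$time_min else numeric(0)
  meal_g <- if (!is.null(meals)) meals$grams else numeric(0)

  for (b in seq_len(nbins)) {
    t0 <- (b - 1L) * 5L
    # CGM: delayed plasma glucose + AR(1) noise
    z <- stats::rnorm(1)
    noise <- sensor$rho * noise +
      sqrt(1 - sensor$rho^2) * sensor$noise_sd * z
    g_del <- G[max(1L, t0 - sensor$delay_min + 1L)]
    sample <- g_del + noise
    cgm_t[b] <- t0; cgm_v[b] <- sample

    if (is.null(open_loop_basal)) {
      act <- controller_step(ctrl, sample, t0, announced_meals = meals)$action
      cmd_bin <- act$basal_rate * 5
      bol <- act$bolus_U
    } else {
      cmd_bin <- open_loop_basal * 5
      bol <- 0
    }

    # blockage on the basal channel
    del_bin <- cmd_bin
    if (!is.null(blockage) && t0 >= blockage$start_time_min) {
      del_bin <- if (blockage$mode == "fixed_amount") {
        max(0, cmd_bin - block_amt)
      } else {
        (1 - block_amt) * cmd_bin
      }
    }
    commanded_U[b] <- cmd_bin
    delivered_U[b] <- del_bin
    blocked_U[b] <- cmd_bin - del_bin
    bolus_U[b] <- bol
    rate <- del_bin / 5                        # U/min

    for (m in 1:5) {
      tm <- t0 + m - 1L                        # minute being integrated
      hit <- which(meal_t == tm)
      if (length(hit)) q <- q + sum(meal_g[hit]) * 1000
      u <- rate + if (m == 1L) bol else 0      # bolus over the first minute
      ra <- params$f_carb * params$ka * q / params$Vg_dL
      ra_vec[tm + 1L] <- ra
      dg <- -params$p1 * g - x * g + params$P0 + ra
      dx <- -params$p2 * x + params$p3 * ip
      dip <- -params$ke * ip + u / params$Vi
      dq <- -params$ka * q
      g <- g + dg; x <- x + dx; ip <- ip + dip; q <- q + dq
      if (!is.finite(g) || g < 0 || g > 2000) {
        stop(sprintf("integration blow-up at t = %d min (G = %g)", tm + 1L, g),
             call. = FALSE)
      }
      G[t0 + m + 1L] <- g
    }
  }

  structure(
    list(
      time_min = 0:nmin,
      glucose = G,
      ra = ra_vec,
      cgm = data.frame(time_min = cgm_t, sgv = cgm_v),
      insulin = data.frame(time_min = cgm_t, commanded_U = commanded_U,
                           delivered_U = delivered_U, blocked_U = blocked_U,
                           bolus_U = bolus_U),
      trace = if (is.null(open_loop_basal)) controller_trace(ctrl) else NULL,
      meals = meals, params = params, config = config, seed = seed
    ),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  tir <- time_in_range(x$glucose)
  cat(sprintf("<sim_result> %s, %.0f h: glucose %.0f-%.0f mg/dL, TIR %.1f%%\n",
              x$params$group, max(x$time_min) / 60, min(x$glucose),
              max(x$glucose), tir[["pct_70_180"]]))
  cat(sprintf("  TDD %.2f U dispensed (%.2f blocked at the infusion site)\n",
              sum(x$insulin$commanded_U) + sum(x$insulin$bolus_U),
              sum(x$insulin$blocked_U)))
  invisible(x)
}

#' @export
plot.sim_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  h <- x$time_min / 60
  graphics::plot(h, x$glucose, type = "l", xlab = "hours",
                 ylab = "glucose (mg/dL)", ylim = range(40, 220, x$glucose),
                 ...)
  graphics::points(x$cgm$time_min / 60, x$cgm$sgv, pch = ".", col = "grey40")
  graphics::abline(h = c(70, 180), lty = 2, col = c("red", "darkgreen"))
  graphics::plot(x$insulin$time_min / 60, x$insulin$delivered_U / 5,
                 type = "s", xlab = "hours", ylab = "basal (U/min)")
  if (any(x$insulin$bolus_U > 0)) {
    graphics::points(x$insulin$time_min[x$insulin$bolus_U > 0] / 60,
                     x$insulin$bolus_U[x$insulin$bolus_U > 0] / 5,
                     pch = 17, col = "blue")
  }
  invisible(x)
}
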