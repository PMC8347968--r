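test_that("initialization prefills one activity horizon of basal history", {
  cfg <- patient_config(ait_minutes = 240, initial_basal_prefill = 0.05)
  st <- controller_init(cfg)
  expect_equal(st$basal_bins[1:48], rep(0.05, 48))
  expect_equal(st$basal_bins[49], 0)
  # different prefills give different initial iIOB on the first cycle
  st2 <- controller_init(patient_config(initial_basal_prefill = 0.10))
  a1 <- controller_step(st, 110, 0)
  a2 <- controller_step(st2, 110, 0)
  tr1 <- controller_trace(st)
  tr2 <- controller_trace(st2)
  expect_equal(tr2$iiob, 2 * tr1$iiob, tolerance = 1e-9)
})

test_that("the controller falls back to the prefill until history accrues", {
  cfg <- patient_config(initial_basal_prefill = 0.06)
  st <- controller_init(cfg)
  out <- controller_step(st, 115, 0)
  expect_true(out$action$insufficient)
  expect_equal(out$action$basal_rate, 0.06 / 5)
  expect_equal(out$action$bolus_U, 0)
  out2 <- controller_step(st, 115, 5)
  expect_false(out2$action$insufficient)
  # zero prefill: flagged start with no insulin on the first cycle
  st0 <- controller_init(patient_config(initial_basal_prefill = 0))
  expect_equal(controller_step(st0, 115, 0)$action$basal_rate, 0)
})

test_that("eventual glycemia and correction follow their formulas", {
  expect_equal(eventual_glycemia(110, 0, 0, 50), 110)
  expect_equal(eventual_glycemia(180, 5, 1, 50), 145)
  expect_equal(eventual_glycemia(100, -5, 0, 50), 85)
  expect_equal(correction_insulin(110, 110, 50), 0)
  expect_equal(correction_insulin(170, 110, 50, 60), 0.1)
  expect_equal(correction_insulin(50, 110, 50, 60), -0.1)
})

test_that("meal boluses divide grams by the carbohydrate ratio", {
  expect_equal(meal_bolus(0, 8), 0)
  expect_equal(meal_bolus(56, 8), 7)
  expect_equal(meal_bolus(37, 10), 3.7)
  expect_error(meal_bolus(10, 0), "> 0")
})

test_that("low glycemia suspends all insulin", {
  cfg <- patient_config(targets = target_range(70, 180))
  st <- controller_init(cfg)
  controller_step(st, 110, 0)
  out <- controller_step(st, 60, 5)
  expect_true(out$action$suspended)
  expect_equal(out$action$basal_rate, 0)
  expect_equal(out$action$bolus_U, 0)
})

test_that("each announced meal is bolused exactly once within the window", {
  cfg <- patient_config(carb_ratio = 8, prebolus_minutes = 30,
                        initial_basal_prefill = 0.05)
  st <- controller_init(cfg)
  meals <- data.frame(time_min = 30, grams = 56)
  boluses <- vapply(seq(0, 60, by = 5), function(t) {
    controller_step(st, 115, t, announced_meals = meals)$action$bolus_U
  }, numeric(1))
  expect_equal(sum(boluses > 0), 1)
  expect_equal(sum(boluses), 7)
  # delivered at the first eligible cycle inside the prebolus window
  expect_equal(which(boluses > 0), 2)  # t = 5 (t = 0 is the warm-up cycle)
})

test_that("prebolusing can be disabled", {
  cfg <- patient_config(carb_ratio = 8, prebolus_enabled = FALSE)
  st <- controller_init(cfg)
  meals <- data.frame(time_min = 30, grams = 56)
  boluses <- vapply(seq(0, 60, by = 5), function(t) {
    controller_step(st, 115, t, announced_meals = meals)$action$bolus_U
  }, numeric(1))
  expect_equal(sum(boluses), 0)
})

test_that("commanded basal converges to the true steady-state requirement", {
  p <- at_target_patient()
  truth <- steady_state_basal(p) * 5
  s <- simulate_patient(p, config = config_for_patient(p, seed = 31),
                        sensor = sensor_model(noise_sd = 0),
                        duration_min = 180, seed = 31)
  est <- mean(utils::tail(s$trace$commanded_basal, 6))
  expect_lt(abs(est - truth) / truth, 0.10)
  expect_true(all(abs(utils::tail(s$glucose, 60) - 110) < 5))
})

test_that("commanded basal respects the temporary-basal bound and suspension", {
  p <- at_target_patient()
  cfg <- config_for_patient(p, seed = 32)
  s <- simulate_patient(p, config = cfg, duration_min = 1440, seed = 32)
  tr <- s$trace
  cap <- cfg$max_temp_basal * 5 / 60
  expect_true(all(tr$commanded_basal >= 0))
  expect_true(all(tr$commanded_basal <= cap + 1e-12))
  expect_true(all(tr$commanded_basal[tr$suspended == 1] == 0))
  expect_true(all(tr$bolus[tr$suspended == 1] == 0))
})

test_that("the trace records the per-cycle quantities", {
  p <- at_target_patient()
  s <- simulate_patient(p, duration_min = 60, seed = 33)
  tr <- s$trace
  expect_equal(nrow(tr), 12)
  expect_true(all(c("time_min", "sgv", "dsgv", "iiob", "iob", "eventual",
                    "target_final", "isf_final", "ebasal", "ebasal_final",
                    "correction", "commanded_basal", "bolus", "lts_flag",
                    "gated", "n_used") %in% names(tr)))
  expect_true(all(tr$ebasal_final <= tr$ebasal + 1e-12))
})
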