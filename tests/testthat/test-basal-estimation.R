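test_that("dSGV is the first difference of the CGM series", {
  expect_equal(compute_dsgv(c(110, 110)), 0)
  expect_equal(compute_dsgv(c(100, 108)), 8)
  expect_equal(compute_dsgv(c(120, 110)), -10)
  expect_equal(compute_dsgv(c(100, 104, 110), all = TRUE), c(4, 6))
  expect_error(compute_dsgv(110), class = "basalloop_insufficient_data")
})

test_that("free fit recovers ISF and basal exactly from collinear duples", {
  d <- regression_duples(c(0, 5, 10), iiob = c(0.03, 0.05, 0.07),
                         dsgv = c(1, 0, -1))
  fit <- fit_free(d)
  expect_equal(unname(coef(fit)), c(50, 0.05), tolerance = 1e-12)
  expect_true(fit$usable)
  expect_equal(residuals(fit), c(0, 0, 0), tolerance = 1e-12)
})

test_that("free fit matches the lm oracle on noisy duples", {
  set.seed(11)
  for (i in 1:40) {
    d <- random_duples(sample(5:40, 1), isf = runif(1, 20, 120),
                       basal = runif(1, 0.02, 0.12), noise = runif(1, 0.2, 3))
    fit <- fit_free(d)
    ref <- oracle_free(d)
    if (fit$usable) {
      expect_equal(unname(coef(fit)), unname(ref), tolerance = 1e-6)
    }
  }
})

test_that("degenerate free fits are flagged", {
  same <- regression_duples(c(0, 5, 10), rep(0.05, 3), c(1, 0, -1))
  expect_error(fit_free(same), "singular")
  expect_error(fit_free(same[1, ]), class = "basalloop_insufficient_data")
  # upward-sloping duples imply glycemia rising with more insulin:
  # physiologically illogical, flagged unusable
  up <- regression_duples(c(0, 5, 10), c(0.03, 0.05, 0.07), c(-1, 0, 1))
  fit <- fit_free(up)
  expect_false(fit$usable)
  expect_match(fit$flag, "illogical")
})

test_that("fixed-ISF fit evaluates the closed form and matches the 1-D oracle", {
  d <- regression_duples(c(0, 5), iiob = c(0.03, 0.07), dsgv = c(1, -1))
  expect_equal(unname(coef(fit_fixed_isf(d, 50))[["ebasal"]]),
               (0 + 50 * 0.10) / (2 * 50), tolerance = 1e-12)
  # a single duple with stable glycemia: basal equals its iIOB
  one <- regression_duples(0, 0.055, 0)
  expect_equal(coef(fit_fixed_isf(one, 40))[["ebasal"]], 0.055)
  set.seed(12)
  for (i in 1:40) {
    d <- random_duples(sample(3:50, 1), noise = runif(1, 0.2, 3))
    isf <- runif(1, 20, 120)
    expect_equal(coef(fit_fixed_isf(d, isf))[["ebasal"]],
                 max(0, oracle_fixed(d, isf)), tolerance = 1e-6)
  }
})

test_that("fixed-ISF fit clamps negative estimates and validates input", {
  d <- regression_duples(c(0, 5), c(0.01, 0.02), c(-30, -30))
  fit <- fit_fixed_isf(d, 50)
  expect_equal(coef(fit)[["ebasal"]], 0)
  expect_true(fit$clamped)
  expect_error(fit_fixed_isf(d, -5), "> 0")
  empty <- regression_duples(numeric(0), numeric(0), numeric(0))
  expect_error(fit_fixed_isf(empty, 50),
               class = "basalloop_insufficient_data")
})

test_that("shifting every dSGV by c shifts the fixed-ISF basal by c/ISF", {
  set.seed(13)
  for (i in 1:20) {
    d <- random_duples(12)
    isf <- runif(1, 25, 100)
    cshift <- runif(1, -2, 2)
    d2 <- d
    d2$dsgv <- d$dsgv + cshift
    # the identity holds up to the clamp at zero infusion
    expect_equal(coef(fit_fixed_isf(d2, isf))[["ebasal"]],
                 max(0, coef(fit_fixed_isf(d, isf))[["ebasal"]] +
                       cshift / isf),
                 tolerance = 1e-9)
  }
})

test_that("noiseless fasting-law duples are recovered exactly", {
  set.seed(14)
  isf_true <- 47
  basal_true <- 0.071
  iiob <- runif(10, 0.02, 0.13)
  d <- regression_duples(seq_len(10) * 5, iiob,
                         -isf_true * (iiob - basal_true))
  expect_equal(unname(coef(fit_free(d))), c(isf_true, basal_true),
               tolerance = 1e-9)
  expect_equal(coef(fit_fixed_isf(d, isf_true))[["ebasal"]], basal_true,
               tolerance = 1e-9)
})

test_that("meal gating invalidates duples during the washout", {
  d <- regression_duples(seq(0, 300, by = 5), rep(0.05, 61), rep(0, 61))
  # no meals: unchanged
  expect_equal(gate_duples(d)$valid, rep(TRUE, 61))
  g <- gate_duples(d, announced_meals = 0, washout_min = 180)
  expect_equal(g$valid, !(d$time_min >= 0 & d$time_min <= 180))
  # a rising trace beyond the detection threshold triggers detection
  rising <- regression_duples(seq(0, 100, by = 5), rep(0.05, 21),
                              c(rep(0, 5), rep(12, 3), rep(2, 13)))
  gd <- gate_duples(rising, washout_min = 60)
  det <- attr(gd, "detected")
  expect_true(length(det) >= 1)
  expect_equal(det[1], 30)  # second consecutive bin above threshold
  expect_false(any(gd$valid[gd$time_min >= det[1] &
                              gd$time_min <= det[1] + 60]))
  expect_true(all(gd$valid[gd$time_min < 25]))
})

test_that("basal trend averages the last 15 min of first derivative", {
  expect_equal(ebasal_trend(c(0.050, 0.048, 0.046, 0.044)), -0.002)
  expect_equal(ebasal_trend(c(0.04, 0.042, 0.044, 0.046)), 0.002)
  expect_equal(ebasal_trend(rep(0.05, 8)), 0)
  expect_equal(ebasal_trend(c(0.05, 0.04)), 0)  # short history: conservative
})

test_that("finalization subtracts falling trends only and never raises", {
  expect_equal(finalize_ebasal(0.044, -0.002), 0.038)
  expect_equal(finalize_ebasal(0.05, 0.01), 0.05)
  expect_equal(finalize_ebasal(0.004, -0.002), 0)
  set.seed(15)
  eb <- runif(200, 0, 0.2)
  tr <- runif(200, -0.05, 0.05)
  out <- mapply(finalize_ebasal, eb, tr)
  expect_true(all(out <= eb + 1e-12))
  expect_true(all(out >= 0))
})
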