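test_that("activity curves conserve insulin and are unimodal", {
  for (model in c("exponential", "triangular")) {
    curve <- activity_curve(240, model)
    expect_length(curve$fractions, 48)
    expect_true(all(curve$fractions >= 0))
    expect_equal(sum(curve$fractions), 1, tolerance = 1e-9)
    # single interior peak: rises then decays
    pk <- which.max(curve$fractions)
    expect_gt(pk, 1)
    expect_lt(pk, 48)
    expect_true(all(diff(curve$fractions[1:pk]) >= 0))
    expect_true(all(diff(curve$fractions[pk:48]) <= 0))
    # activity nearly exhausted at the AIT horizon
    expect_lt(curve$fractions[48], max(curve$fractions) / 10)
  }
})

test_that("shorter AIT concentrates activity into a larger peak", {
  short <- activity_curve(180, "exponential", peak_minutes = 75)
  long <- activity_curve(300, "exponential", peak_minutes = 75)
  expect_gt(max(short$fractions), max(long$fractions))
})

test_that("invalid curve durations are configuration errors", {
  expect_error(activity_curve(-60), "positive")
  expect_error(activity_curve(0), "positive")
  expect_error(activity_curve(242), "multiple")
  expect_error(activity_curve(240, peak_minutes = 240), "peak_minutes")
  expect_error(activity_curve(240, "exponential", peak_minutes = 130),
               "ait_minutes / 2")
})

test_that("dose decomposition conserves the dose and is linear", {
  set.seed(101)
  for (i in 1:25) {
    ait <- sample(c(120, 180, 240, 300, 360), 1)
    model <- sample(c("exponential", "triangular"), 1)
    curve <- activity_curve(ait, model, peak_minutes = min(50, ait / 2 - 5))
    amount <- runif(1, 0.1, 10)
    t0 <- sample(0:100, 1) * 5
    s <- decompose_dose(list(time_min = t0, amount_U = amount), curve)
    expect_equal(sum(s$values), amount, tolerance = 1e-9)
    expect_true(all(s$values >= 0))
    expect_equal(s$start_time_min, t0)
    # homogeneity
    s2 <- decompose_dose(list(time_min = t0, amount_U = 2 * amount), curve)
    expect_equal(s2$values, 2 * s$values, tolerance = 1e-12)
  }
})

test_that("a dose given 2 h ago acts now at its 120-min fraction", {
  curve <- activity_curve(240)
  s <- decompose_dose(list(time_min = -120, amount_U = 0.5), curve)
  now <- which(iseries_times(s) == 0)
  expect_equal(s$values[now], 0.5 * curve$fractions[25])  # 120-min bin
})

test_that("iIOB aggregation is additive and handles overlap", {
  curve <- activity_curve(240)
  doses <- dose_events(c(-120, -60), c(0.5, 2.0))
  agg <- aggregate_iiob(doses, curve, window = c(-120, 180))
  t <- iseries_times(agg)
  d1 <- decompose_dose(list(time_min = -120, amount_U = 0.5), curve)
  d2 <- decompose_dose(list(time_min = -60, amount_U = 2.0), curve)
  # before dose 2 starts, the aggregate is dose 1's decomposition alone
  pre <- t < -60
  expect_equal(agg$values[pre], d1$values[seq_len(sum(pre))])
  # where both act, the aggregate is their sum
  both <- t >= -60 & t < 120
  expect_equal(agg$values[both],
               d1$values[t[both] / 5 + 25] + d2$values[t[both] / 5 + 13])
  # the overlapped peak falls during dose-2 activity
  expect_gte(t[which.max(agg$values)], -60)
  # additivity: aggregate of one dose equals its decomposition
  one <- aggregate_iiob(dose_events(0, 1.5), curve)
  expect_equal(one$values, decompose_dose(list(time_min = 0, amount_U = 1.5),
                                          curve)$values)
  # two identical doses double one
  two <- aggregate_iiob(dose_events(c(0, 0), c(1.5, 1.5)), curve)
  expect_equal(two$values, 2 * one$values, tolerance = 1e-12)
  # empty dose list: zero series, not an error
  z <- aggregate_iiob(dose_events(), curve, window = c(0, 60))
  expect_equal(z$values, rep(0, 12))
})

test_that("IOB matches its definition on the worked cases", {
  curve <- activity_curve(240)
  expect_equal(compute_iob(dose_events(0, 1), curve, 0, t = 0), 1,
               tolerance = 1e-9)
  expect_equal(compute_iob(dose_events(), curve, 0, t = 0), 0)
  expect_equal(compute_iob(dose_events(0, 1), curve, 0.02, t = 0),
               1 - 48 * 0.02, tolerance = 1e-9)
})

test_that("IOB equals the brute-force double loop on random histories", {
  set.seed(202)
  for (i in 1:30) {
    curve <- activity_curve(sample(c(180, 240, 300), 1))
    nd <- sample(1:8, 1)
    doses <- dose_events(sort(sample(seq(-240, 240, by = 5), nd)),
                         runif(nd, 0.05, 5))
    basal <- runif(1, 0, 0.1)
    t <- sample(seq(-60, 300, by = 5), 1)
    expect_equal(compute_iob(doses, curve, basal, t),
                 brute_iob(doses, curve, basal, t), tolerance = 1e-9)
  }
})

test_that("aggregated iIOB matches the per-bin brute force", {
  set.seed(303)
  curve <- activity_curve(240)
  doses <- dose_events(sort(sample(seq(0, 200, by = 5), 6)),
                       runif(6, 0.1, 3))
  agg <- aggregate_iiob(doses, curve)
  t <- iseries_times(agg)
  for (j in seq(1, length(t), by = 7)) {
    expect_equal(agg$values[j], brute_iiob_at(doses, curve, t[j]),
                 tolerance = 1e-12)
  }
})

test_that("curve misconfiguration error is signed and integrates to zero", {
  true4h <- activity_curve(240)
  cfg3h <- activity_curve(180)
  doses <- dose_events(0, 1)
  err <- iiob_misconfiguration_error(true4h, cfg3h, doses)
  expect_equal(sum(err$values), 0, tolerance = 1e-9)
  # a too-short configured AIT over-estimates early activity and
  # under-estimates the tail
  expect_gt(err$values[2], 0)
  expect_lt(err$values[40], 0)
  # identical curves: identically zero
  z <- iiob_misconfiguration_error(true4h, activity_curve(240), doses)
  expect_equal(z$values, rep(0, length(z$values)))
  # mismatched bin sizes rejected
  expect_error(
    iiob_misconfiguration_error(true4h, activity_curve(240, bin_minutes = 10),
                                doses),
    "bin_minutes"
  )
})

test_that("dose events are validated", {
  expect_error(dose_events(0, -1), "> 0")
  expect_error(dose_events(0, 1, "snack"), "kind")
  expect_silent(dose_events(-120, 0.5, "basal_bin"))
})
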