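# Independent oracles used to check the closed-form implementations.

# Brute-force IOB: double loop over bins and doses, literal evaluation of
# "sum over future bins of (iIOB_n - basal) up to the last active bin".
brute_iob <- function(doses, curve, basal_per_bin = 0, t = 0) {
  bm <- curve$bin_minutes
  if (nrow(doses) == 0) return(0)
  st <- round(doses$time_min / bm) * bm
  end <- max(st) + curve$ait_minutes
  if (end <= t) return(0)
  total <- 0
  for (b in seq(t, end - bm, by = bm)) {
    iiob <- 0
    for (i in seq_len(nrow(doses))) {
      k <- (b - st[i]) / bm
      if (k >= 0 && k < length(curve$fractions)) {
        iiob <- iiob + doses$amount_U[i] * curve$fractions[k + 1]
      }
    }
    total <- total + iiob - basal_per_bin
  }
  total
}

# Brute-force iIOB at a single bin (sum over doses).
brute_iiob_at <- function(doses, curve, b) {
  bm <- curve$bin_minutes
  st <- round(doses$time_min / bm) * bm
  iiob <- 0
  for (i in seq_len(nrow(doses))) {
    k <- (b - st[i]) / bm
    if (k >= 0 && k < length(curve$fractions)) {
      iiob <- iiob + doses$amount_U[i] * curve$fractions[k + 1]
    }
  }
  iiob
}

# Independent least-squares oracles: lm() for the free two-parameter fit,
# 1-D numerical SSE minimization for the fixed-slope fit.
oracle_free <- function(duples) {
  m <- stats::lm(dsgv ~ iiob, data = duples)
  slope <- unname(stats::coef(m)[2])
  intercept <- unname(stats::coef(m)[1])
  c(isf = -slope, ebasal = -intercept / slope)
}

oracle_fixed <- function(duples, isf) {
  sse <- function(b) sum((duples$dsgv + isf * (duples$iiob - b))^2)
  stats::optimize(sse, interval = c(-2, 2), tol = 1e-12)$minimum
}

# Random duple sets drawn around the fasting relation with noise.
random_duples <- function(n, isf = 50, basal = 0.06, noise = 1) {
  iiob <- stats::runif(n, 0, 0.15)
  dsgv <- -isf * (iiob - basal) + stats::rnorm(n, sd = noise)
  regression_duples(seq_len(n) * 5, iiob, dsgv)
}

# A virtual patient whose fasting equilibrium sits at the controller's
# desired target, so the steady-state basal is the basal the loop should
# find.
at_target_patient <- function() {
  vp_params("adult", Gb = 110)
}
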