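---
title: "Dynamic basal-needs estimation in a closed insulin loop: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic basal-needs estimation in a closed insulin loop: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(basalloop)
```

## The problem

A closed-loop insulin delivery system ("artificial pancreas") must know the
patient's *basal needs* — the insulin rate that keeps fasting glycemia flat —
yet those needs drift with exercise, illness, meals of low glycemic index,
or a partly blocked infusion site. Most systems treat the basal profile as a
fixed, manually tuned configuration. `basalloop` implements an estimator
that infers basal needs *on-line* from two signals every pump already has:
the CGM glucose trace and its own dose history.

## Insulin decomposition: iIOB and IOB

One unit of rapid-acting insulin acts over several hours, described by an
activity curve over the active insulin time (AIT). On a 5-min grid aligned
with CGM sampling, the curve is a vector of fractions summing to exactly 1:
the share of the unit absorbed in each bin. Any dose is *decomposed* by this
curve into "instantaneous boluses", and the instantaneous insulin on board
(iIOB) at a bin is the sum over all past doses of their instantaneous
contributions. Conservation (each decomposition sums to the dose) and
linearity are the load-bearing invariants and are property-tested.

The analytic form of the curve is a modelling choice. The default is the
field-standard exponential activity model
$a(t) \propto t\,(1 - t/\mathrm{AIT})\,e^{-t/\tau}$, with $\tau$ fixed so
the peak falls at `peak_minutes` (default 75 min); it is zero at both ends
of the horizon and unimodal, and requires the peak in the first half of the
AIT. A triangular family is available as a cross-check. Both are evaluated
at bin midpoints and renormalized, so conservation is exact by
construction; dose times are snapped to the nearest bin start.

Insulin on board (IOB) nets pending insulin against basal needs
(`compute_iob()`): the sum over future active bins of `iIOB - basal`. Inside
the controller the *surplus* form of the same quantity is used — each past
dose's deviation from estimated basal needs weighted by the share of its
activity still to come — which corresponds to evaluating the IOB sum under
the convention that basal delivery continues at the estimated rate. The two
forms differ by a constant that depends only on the curve; the surplus form
is zero at steady delivery, equals a bolus right after the bolus, and goes
negative after a suspension, which is exactly the signal the eventual-
glycemia prediction needs. With the literal truncated sum, a controller at
perfect steady state would see a spurious deficit of roughly two units and
over-correct indefinitely.

## The estimator

Fasting glycemia obeys, to first order,
$\mathrm{dSGV} = -\mathrm{ISF}\,(\mathrm{iIOB} - \mathrm{Basal})$:
glucose falls when more insulin acts than the body needs. Ordinary least
squares on recent (iIOB, dSGV) duples would recover both the insulin
sensitivity factor (minus the slope) and the basal needs (the zero
crossing), but with few, noisy, closely spaced duples the slope is fragile
and can even turn positive — an "illogical sensitivity" that `fit_free()`
flags and refuses to use. The working estimator `fit_fixed_isf()` pins the
slope at the patient's configured ISF, reducing the problem to a one-
parameter fit with the closed form

$$\hat b = \frac{\sum_i \mathrm{dSGV}_i + \mathrm{ISF}\sum_i \mathrm{iIOB}_i}
               {N\,\mathrm{ISF}},$$

the exact minimizer of the fixed-slope sum of squares. Tests verify both
fits against independent oracles (`lm()` and 1-D numerical minimization)
and exact recovery from noiseless collinear duples.

Three protections surround the regression:

* **Meal gating.** Carbohydrate absorption breaks the fasting law, so duples
  within a washout (default 180 min) after an announced meal — or after a
  detected one (dSGV above +10 mg/dL per bin for 2 consecutive bins) — are
  discarded and the estimator holds its last finalized value. The held value
  is appended to the estimate history so the trend flattens rather than
  extrapolating stale dynamics; the alternative (shrinking the window) would
  make the first post-meal estimates jumpy.
* **Trend.** The estimate's trend is the mean of its last three first
  differences (15 min of derivative), a compromise between response time
  and CGM noise.
* **Safe finalization.** Insulin cannot be removed once dosed, so a falling
  trend is extrapolated 15 min ahead (the typical CGM delay) and subtracted,
  while a rising trend is ignored — more insulin can always be added later.
  The finalized estimate never exceeds the raw one and is clamped at zero.

The duple window holds N = 12 duples (1 h) by default: large enough to
average sensor noise through the telescoping sum of differences, small
enough to track needs that change on the hour scale.

## The controller cycle

Every 5 min the controller: stores the CGM sample and its derivative;
computes iIOB (basal and bolus insulin separately) and the surplus IOB;
adapts the ISF to current glycemia,
$\mathrm{ISF} = \mathrm{ISF}_{target} - \mathrm{ratio} \cdot |SGV - target|$,
floored at a configured minimum; predicts *eventual glycemia* as the sample
plus a 15-min trend extrapolation minus the glycemic drop the surplus IOB
will still cause; updates the low-threshold-suspend state; derives the
glycemic target (midpoint of the configured range, raised dynamically
toward the glucose level when running high, clamped into
[desired, range top]); re-estimates basal needs; adds correction insulin
that pays the eventual-vs-target error back through the basal channel over
a 60-min horizon; clamps the total command into [0, maximum temporary
basal]; and handles announced meals with a single carbohydrate-ratio bolus
inside the prebolus window.

Suspension is unconditional whenever current *or* eventual glycemia falls
below the range floor, zeroing both basal and bolus output (a bolus due
during a suspension is deferred, not lost, while the meal stays inside the
prebolus window); after resuming, a caution flag pins the target at the
range top for exactly 15 min. The ISF adaptation uses the current sensor
value as written in its defining relation, while the correction error is
computed against eventual glycemia — the enumerated loop wants the error
against the prediction, and the two choices are logged separately in the
trace.

Start-up uses a basal-history prefill over one activity horizon (a
per-patient prior, deliberately jittered ±20% in the experiments), and the
controller falls back to commanding the prefill until two CGM samples
exist.

## The virtual patient

Experiments need ground truth, which no clinical trace provides. The
virtual patient is a Bergman-type minimal model with a one-compartment gut:

$$\dot G = -p_1 G - X G + P_0 + f k_a Q / V_g,\qquad
  \dot X = -p_2 X + p_3 I_p,\qquad
  \dot I_p = -k_e I_p + u/V_i,\qquad
  \dot Q = -k_a Q.$$

It was chosen over replicating a full simulator cohort because the claims
under test concern the *controller*, and this model has closed-form ground
truth: the steady-state basal `steady_state_basal()` and an analytic
sensitivity `patient_isf()` — so basal recovery is testable to a stated
tolerance rather than by eyeball. An adapter seam is simple: anything that
accepts a 5-min CGM sample and returns an insulin action satisfies the
controller's contract (`controller_step()`).

CGM sensing is a pure 10-min delay (configurable within the physiological
10–20 min) plus AR(1) noise with marginal sd 3 mg/dL and lag-one
correlation 0.7 — the delay range is physiological, the noise magnitude a
typical modern-sensor figure. Physiology is integrated by forward Euler at
1-min substeps; all rate constants are well below 0.1/min so the step is
comfortably inside the stability region, and the scheme keeps the
closed-loop event structure (5-min commands, meal impulses, per-bin
blockage) exact. Non-physical trajectories abort with a diagnostic.

The seeded cohort generator draws 10 adults, 10 adolescents and 10 children
from group-specific ranges (basal 0.8–1.3, 0.55–0.95 and 0.25–0.45 U/h;
correspondingly scaled distribution volumes), reproducing the qualitative
adult-to-child ordering of insulin needs. Per-patient controller
configurations are derived from the patient's own analytic quantities: ISF
from `patient_isf()`, carbohydrate ratio from the carb-to-glucose balance
$CR = ISF \cdot V_g / (1000 f)$, maximum temporary basal at four times the
steady basal, prebolus lead drawn in 10–60 min.

## The four experiments

Each batch simulates all 30 patients for 24 h: (1) fasting; (2) four meals
(56 g at 07:00, 37 g at 13:00, 9 g at 17:00, 38 g at 20:00 — 140 g of
fast-absorption carbohydrate); (3) fasting with an infusion blockage from
12:00 withholding half of each patient's predetermined (steady-state)
basal; (4) meals plus blockage. Time in range is computed on plasma
glucose at 1-min resolution in the bands <70, 70–180, >180 and >250 mg/dL.

TDD accounting sums pump-*dispensed* insulin: under a blockage the insulin
leaves the reservoir but is not absorbed, so the dispensed TDD of a
blockage day exceeds its fasting twin (the controller commands more) while
the increment stays below the blocked amount — the patient rides slightly
higher glycemia, where the dynamic target deliberately slows the loop, and
absorbs a little less insulin overall. Batches sharing a seed share noise
streams and configurations, so fasting and blockage traces are
bit-identical before 12:00.

## What the tests do and do not show

The synthetic experiments demonstrate: conservation and oracle equivalence
of the kinetics and estimators; closed-loop recovery of a known basal
requirement within 10% (noiseless) and 20% (sd 3 noise) after ~2 h of
fasting at target; full-cohort 24-h fasting and blockage days entirely
within 70–180 mg/dL; the dispensed-TDD ordering above; and degraded control
(larger plasma-glucose variance under identical noise) when the configured
AIT is half the appropriate one — the misconfiguration analysis also checks
that the iIOB error series of a mismatched curve integrates to zero, since
both curves conserve insulin.

They do not show performance on real physiology: the minimal model has a
single glucose compartment, no exercise, illness, circadian insulin-need
variation, mixed-meal or high-fat dynamics, and its simple gut model makes
meals fast and regular. Meal days leave range transiently (children worst,
adults best, as expected from their larger glycemic excursions per gram);
brief post-meal hypoglycemia can occur in small children on this synthetic
physiology, a known limitation of the deliberately simple carb-ratio
derivation rather than of the estimator. Pump quantization and dual-hormone
control are out of scope.

## Numerical choices

* 5-min bin grid everywhere; dose times snapped to bin starts.
* Activity fractions renormalized so conservation is exact (1e-9 in tests).
* Exponential family requires `peak < AIT/2`; errors otherwise.
* Negative basal estimates clamp to 0 and are flagged, never propagated.
* Trend needs 4 history points; shorter histories yield trend 0.
* Correction horizon 60 min; the command is bounded by the maximum
  temporary basal *after* adding the correction, and zeroed by suspension.
* Forward Euler, 1-min substeps; blow-up guard aborts outside (0, 2000]
  mg/dL.
* Every stochastic path (cohort draw, config jitter, sensor noise) is
  seeded; batch runs derive per-patient seeds as `seed + 101 * patient`.

## A worked fasting day

```{r fasting, eval = FALSE}
p <- vp_params("adult", Gb = 110)
s <- simulate_patient(p, duration_min = 1440, seed = 7)
print(s)
plot(s)
time_in_range(s)
steady_state_basal(p) * 5         # true U/bin, for comparison with
tail(s$trace$ebasal_final, 3)     # the estimator's finalized output
```

Cohort-scale experiments go through `make_cohort()` and `run_batch()`; the
repository's `scripts/acceptance.R` reruns the fasting and blockage batches
end to end and writes their in-range percentages as JSON.
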