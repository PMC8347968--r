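# basalloop

Dynamic estimation of basal insulin needs inside a closed-loop
glucose controller, with a self-contained virtual patient for desk-scale
in-silico experiments.

## The problem

People with type-1 diabetes on pump therapy need a *basal profile*: the
background insulin rate that keeps fasting glycemia flat. Needs drift with
exercise, illness, slow meals or a partly blocked infusion set, yet most
closed-loop systems treat the profile as fixed configuration. `basalloop`
estimates basal needs on-line from two signals every pump has — the CGM
trace and the dose history — and feeds the estimate into a single-hormone
closed-loop controller.

## The method

Past doses are decomposed through the insulin activity curve into
per-5-min *instantaneous boluses*; their sum across doses is the
instantaneous insulin on board, iIOB. In fasting, glucose obeys

    dSGV = -ISF * (iIOB - Basal)

where dSGV is the CGM first difference and ISF the insulin sensitivity
factor (mg/dL per U). A free least-squares fit of this line is fragile on
few noisy duples (the slope can even turn positive, an illogical
sensitivity which the package flags), so the working estimator pins the
slope at the configured ISF and solves the one-parameter problem in closed
form:

    eBasal = (sum(dSGV) + ISF * sum(iIOB)) / (N * ISF)

Duples within 3 h of an announced or detected meal are discarded; the
estimate's 15-min trend is subtracted when falling (never added when
rising — dosed insulin cannot be removed, more can always be added); the
controller adds a correction for the eventual-glycemia error, adapts the
ISF and the glycemic target to current glycemia, and suspends all insulin
whenever current or eventual glycemia drops below the target floor.

The virtual patient is a Bergman-type minimal model with a one-compartment
gut, CGM delay and AR(1) sensor noise, and an infusion-blockage mechanism;
its steady-state basal requirement is available in closed form, which makes
estimator accuracy testable.

## A worked example

A 24-hour closed-loop fasting day on a virtual adult whose fasting
equilibrium sits at the controller's desired target (110 mg/dL):

```r
library(basalloop)
p <- vp_params("adult", Gb = 110)
steady_state_basal(p) * 5   # true basal requirement, U per 5-min bin
#> [1] 0.08470588

s <- simulate_patient(p, duration_min = 1440, seed = 7)
print(s)
#> <sim_result> adult, 24 h: glucose 110-124 mg/dL, TIR 100.0%
#>   TDD 21.50 U dispensed (0.00 blocked at the infusion site)

round(time_in_range(s), 2)
#>  pct_below_70    pct_70_180 pct_above_180 pct_above_250
#>             0           100             0             0
```

Glucose stays inside 70–180 mg/dL all day and the finalized basal estimate
tracks the true requirement (the conservative trend rule keeps it at or
below the raw estimate). Cohort experiments mirror the four scenarios —
fasting, meals, infusion blockage from 12:00, both:

```r
co <- make_cohort(10, 10, 10, seed = 42)   # adults, adolescents, children
b1 <- run_batch(1, co, seed = 42)          # 24-h fasting
print(b1)
#> <batch_result> batch 1 (fasting), 30 patients, seed 42
#>
#> Percentage of time in range (plasma glucose):
#>                   BG<70  70<BG<180   BG>180   BG>250
#>   adolescent       0.0%     100.0%     0.0%     0.0%
#>   adult            0.0%     100.0%     0.0%     0.0%
#>   child            0.0%     100.0%     0.0%     0.0%
#>
#> TDD: mean 19.20 U (range 7.40-37.45 U)
```

`run_batch(3, ...)` adds a blockage withholding half of each patient's
predetermined basal from 12:00; `tdd_comparison()` pairs the two runs and
shows, per patient, a positive dispensed-TDD increment that stays below the
blocked insulin. A thin command-line front end lives at
`inst/cli/basalloop.R` (`run-batch`, `make-cohort`, `report`).

See the vignette (`vignettes/closed-loop-basal-estimation.Rmd`) for the
model, the safety rules and the design rationale.

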