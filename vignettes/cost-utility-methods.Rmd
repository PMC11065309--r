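---
title: "Cost-utility modelling of automated ward monitoring: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-utility modelling of automated ward monitoring: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monitorCE)
```

This vignette documents the model implemented by `monitorCE`, the
assumptions behind every distributional choice, the calibration of the
synthetic patient-level cohort, and the design decisions taken where
the methodology left the design genuinely open.

## The decision problem

An electronic automated advisory vital-signs monitoring and
notification system (continuous sensors, automated early-warning-score
calculation, automatic escalation to clinical teams) is compared with
standard spot-check monitoring for adults admitted to two general wards
(gastroenterology and respiratory) of a UK district general hospital.
Two horizons are analysed from the NHS perspective:

* **short term (inpatient episode)** — cost per serious adverse event
  avoided, using adjusted per-arm episode costs and adjusted mean event
  counts;
* **lifetime (cost per QALY)** — the consequences of the principal
  discharge state are extrapolated with published lifetime costs and
  quality-adjusted life expectancies (QALEs).

## Model structure

The model is a one-shot decision tree, not a Markov model: each arm
distributes patients over discharge states and attaches lifetime
payoffs to the state reached. Per arm:

$$\mathrm{QALE} = p_{\text{no}}\, q_{\text{no}} +
  p_{\text{ev}} \sum_e \pi_e q_e + p_{\text{death}} \cdot 0$$

$$\mathrm{COST} = \text{episode cost} + p_{\text{no}}\, c_{\text{no}} +
  p_{\text{ev}} \sum_e \pi_e \tilde c_e + p_{\text{death}} \cdot 0$$

with $(p_{\text{no}}, p_{\text{ev}}, p_{\text{death}})$ the
discharge-state probabilities, $\pi$ the distribution over the seven
non-fatal principal events among survivors of an event, and $q_s, c_s$
the state QALEs and discounted lifetime costs. Conventions:

* **Death leaf.** Inpatient death carries zero lifetime cost and zero
  QALE. This is implied rather than stated by the source tables; with
  this convention the engine reproduces the published per-arm QALEs to
  within 0.0003 QALYs and lifetime costs to within 0.02%, which we take
  as confirmation.
* **No-event state.** Patients discharged without a serious event get a
  ward-mix weighted average of chronic-condition profiles:
  `mix × ward2(respiratory) + (1 − mix) × ward1(gastroenterology)`,
  with `mix = 0.56` (the observed share of pulmonology admissions)
  exposed as an input rather than hard-coded.
* **Cost carry-forward.** An event state is only allowed to *raise* the
  lifetime cost relative to no event: the one state with a cheaper
  published profile (pulmonary embolism) is assigned the no-event cost.
  Its QALE remains its own. The flag is per-state in the configuration,
  not hard-wired to pulmonary embolism.
* **Episode costs are inputs.** The adjusted per-arm inpatient episode
  costs (which already include device costs) come from patient-level
  regression, not from re-composition of tariff elements inside the
  engine; the engine treats them as opaque means with 95% central
  ranges.

## Parameters and units

All monetary values are GBP at 2020/21 prices, stored at full precision
and rounded only for display (2 dp for GBP, 4 dp for QALYs). Lifetime
costs and QALEs are *already discounted* at 3.5% a year; the
`discounted_qale()` helper (annual utility × annuity factor over the
17.74-year life expectancy of the model population) exists to
reconstruct or replace them. The key tunables:

| input | default | unit | role |
|---|---|---|---|
| `ward_mix_pulmonology` | 0.56 | proportion | no-event state weighting |
| `discount_rate` | 0.035 | 1/year | annuity factor, EAC device costing |
| `product_life` | 5 | years | device annualization |
| `cableless_rate` | 0.123 | proportion | variable sensor cost |
| `beds`, `mean_los` | 54; 8.62/8.90 | n; days | ward throughput |
| `occupancy` | 1.0 | proportion | throughput scaling |
| `sd_fraction` (PSA) | 0.2 | — | sd/mean of lifetime cost & QALE draws |
| `lambda` | 20000 | GBP/QALY | net-benefit threshold |

Device costing divides annualized fixed plus variable cost by the
annual throughput `(365/LOS) × beds × occupancy`, kept unrounded in all
divisions. 100% occupancy follows usual NHS ward practice and is an
explicit knob. Variable cost assumes one cableless sensor per monitored
patient episode (`sensors_per_patient` is exposed because consumption
per episode is not pinned down by the sources; the published
100%-usage ICER is not exactly reproducible under the one-sensor
reading, and we document rather than resolve that discrepancy).

## Probabilistic sensitivity analysis

Each of the (default) 10,000 draws samples every uncertain input:

* **Discharge-state probabilities**: Dirichlet over the per-arm
  effective counts (e.g. 3579/24/184 of 3787). The published label
  "Dirichlet-multinomial" is ambiguous; sampling the conjugate
  Dirichlet directly is standard PSA practice and is the default, with
  compound multinomial resampling behind `compound = TRUE`.
* **Principal-event distributions**: Dirichlet over the published
  concentrations. The intervention arm's concentrations are
  near-degenerate (total ≈ 24, dominated by ICU admission); vectors
  whose *total* falls below `1e-6` fall back to the point estimates,
  and gamma variates that underflow to zero for tiny shapes are
  harmless because rows are renormalized.
* **Lifetime costs**: Gamma with shape $1/f^2$ and mean preserved,
  where $f$ is `sd_fraction`; $f = 0.2$ gives the published shape 25.
* **QALEs**: Normal with sd $f \times$ mean, truncated at zero by
  resampling (negative life expectancy is meaningless; the sources do
  not address negative draws).
* **Episode costs**: only a mean and a bootstrap 95% central range are
  published, so draws come from a Gamma moment-matched to the mean and
  the range-implied sd `(high − low)/3.92` — costs are positive and
  right-skewed, making a Gamma the natural two-moment family. This is
  a stand-in for resampling the original patient-level bootstrap, and
  contributes a few percentage points of method uncertainty to the
  CEAC beyond Monte-Carlo error.
* **Correlation**: one draw per input row. Health states are shared
  wherever both arms reference them (all lifetime cost/QALE states,
  including the no-event wards), because the input table lists one
  distribution per state; discharge-state and principal-event
  distributions and episode costs are arm-specific and independent.
  Resource-use and device-price inputs are fixed in the PSA, as the
  input table marks them.

The CEAC reports, per willingness-to-pay $\lambda$, the fraction of
draws with $\lambda \Delta Q - \Delta C > 0$; at $\lambda = 0$ it
equals the probability of cost saving and for large $\lambda$ it
approaches the probability of a QALY gain. With the default inputs the
probability of cost-effectiveness at £20,000/QALY is about 81%, stable
within a few points across `sd_fraction` 0.1/0.2/0.4. Because state
draws are shared between arms, much of their uncertainty cancels in
the increments: the spread of $\Delta C$ reacts only weakly to
`sd_fraction` below 0.2, which is why scenario outputs separate
clearly only between the extreme fractions.

## Threshold and sensitivity machinery

Device-cost changes propagate into the comparison as an additive
per-patient adjustment of the intervention arm's episode cost relative
to the base device cost (the episode costs already embed the base
device cost, so recomputing them from scratch is neither possible nor
needed). Consequently:

* the short-term incremental cost is affine in the cableless rate with
  slope equal to the sensor price, and the dominance boundary (the rate
  at which the £12.17 episode saving is exhausted) is unique — located
  by bisection to ±0.001, at ≈ 0.236;
* the threshold device cost (per-patient price at which the
  intervention stops being cost saving during the episode) is the base
  per-patient device cost plus the base saving, ≈ £32.17;
* the discount rate enters one-way sensitivity through the
  equivalent-annual-cost annualization only; lifetime values are
  literature inputs already discounted at 3.5% and cannot be
  re-discounted from their printed totals.

Both break-even quantities are defined on the *short-term* incremental
hospital cost; the lifetime saving (≈ £55.8) would give boundaries
several times larger, which is inconsistent with the published
break-even points — hence the short-term definition.

## Synthetic cohort and estimation

No public patient-level data exist for this study population, so the
package generates cohorts with the statistical structure the
estimation stage assumes, and the estimation stage recovers the model
inputs from them. The generator's defaults are the study conditions:

* **age**: `round(101 − X)` with `X ~ Gamma(3.5991, scale 9.1691)`,
  truncated to [17, 100] — a left-skewed distribution calibrated to
  median 71 and IQR 59–81 (only summary statistics are available);
* **sex / ward**: Bernoulli, 52% female, 56% pulmonology;
* **NEWS on admission**: discretized negative binomial with mean 3.15
  and sd 2.82 (size 2.066), truncated to 0–20;
* **event counts**: NB2 negative binomial with log link on arm, age,
  sex, ward and NEWS. Per-arm intercepts are calibrated *exactly* by
  enumeration over the discrete covariate grid so the marginal means
  equal the adjusted per-arm targets (0.0666 / 0.0933); per-arm
  dispersions are calibrated so P(count = 0) equals each arm's
  no-event probability, coupling the count model to the discharge
  multinomial;
* **discharge states**: a patient with zero events is "no event";
  a patient with events draws death vs principal-event category from
  the configured per-arm multinomial renormalized on the event branch.
  Patients with several events are represented by their principal
  (worst) event only, ordering severity by ascending QALE;
* **episode costs**: Gamma with log-link covariate model, per-arm
  intercepts calibrated exactly to the adjusted means
  (2046.99 / 2059.16); the patient-level shape of 0.5 (CV ≈ 1.4)
  reproduces bootstrap central ranges of the published width at
  n = 3787;
* **length of stay**: Gamma with per-arm means 8.62/8.90 days and
  shape 1.2, putting the median near the observed 6 days; ICU days
  attach only to ICU-admission events (mean 3 days).

This construction makes every marginal the estimation stage targets
exact in expectation while keeping the record-level invariant
(`event_count > 0` ⇔ event or death). What it does *not* emulate:
residual correlation between NEWS, events, length of stay and costs
beyond the shared covariate effects; readmissions; event clustering in
time; and any difference between wards beyond a multiplicative cost
and event effect. Passing parameter-recovery tests therefore shows the
estimators are consistent under the assumed structure, not that the
structure captures every feature of real ward data.

Estimation mirrors the published analysis: negative-binomial
regression for counts, gamma/log GLM for costs, multinomial logit for
discharge states — each adjusted for arm, age, sex, ward and NEWS
(entered continuously; banding belongs to subgroup analysis) — with
"adjusted per-arm means" defined by recycled-prediction
(counterfactual) standardization: predict every patient under each arm
and average. With no covariates this reduces exactly to raw arm means.
Uncertainty uses the non-parametric percentile bootstrap (the sources
say only "95% central range", so percentile rather than BCa), with
failed resamples redrawn up to a retry cap. The within-survivor
principal-event distribution is estimated as normalized empirical
frequencies per arm: with seven categories and only a few dozen
events, a second multinomial logit is unidentifiable.

## Subgroups

Strategies are stratified by age band (17–74 / 75+), NEWS band
(0–2 / 3–5 / 6+) or ward (standing in for the respiratory/digestive
primary-diagnosis chapters, which the synthetic records do not carry).
Stratum parameter sets are re-estimated covariate-free from the
stratified cohort; lifetime states and device inputs are carried over
unless supplied per stratum, because the stratum-adjusted secondary
parameters of the original analysis are not published in the main
text. The league table ranks strategies by net monetary benefit at
£20,000/QALY (ranking by net health benefit is identical at any single
threshold).

## Numerical choices and degenerate inputs

* Probability vectors must sum to 1 within 1e-9 (discharge states) or
  1e-6 (principal events, stored at 8 printed decimals); Gamma means
  must match stated costs within 0.5%. Validation *reports* all
  violations; loading raises with the full list.
* The stored Gamma rate for acute pulmonary oedema follows its
  £19,198 point estimate (shape 25, scale 767.92, shared with the
  other states costed from the same source); PSA regenerates Gamma
  parameters from `sd_fraction` in any case.
* `sd_fraction = 0` collapses every draw to the point estimates — the
  documented degenerate limit, under which the CEAC becomes the 0/1
  step of the deterministic net benefit.
* Ties in the league table share a rank (`ties.method = "min"`).
* Single-category discharge outcomes bypass the logit and return a
  degenerate probability vector; empty principal-event categories get
  probability zero with a warning, never an error.
* A global pipeline seed is fanned out as `seed + 1000 × stage index`,
  so each stage is independently reproducible.

## Problem sizes used in the test suite

The packaged tests exercise the generator and estimators at cohort
sizes between 3,787 (the analysis sample size, used for the
100-replication parameter-recovery experiment) and 100,000 (moment
checks), the PSA at 10,000 draws for headline figures and 50,000–100,000
draws for distributional moment checks; these sizes give Monte-Carlo
standard errors comfortably below the tolerances asserted.

## Known limitations

* Maintenance, training and staffing-opportunity costs of either
  monitoring approach are out of scope, as in the source analysis.
* The model is a single-episode tree: no readmissions, no time
  dynamics within the episode, no Markov extrapolation.
* Lifetime payoffs come from published condition-specific estimates,
  not patient-level follow-up; their `sd_fraction` uncertainty model
  is an assumption, tested only by scenario analysis.
* The episode-cost PSA distribution is moment-matched rather than the
  original bootstrap, adding method uncertainty to acceptability
  estimates (a few percentage points at most, by scenario comparison).
* The synthetic cohort is a structural stand-in; conclusions about
  real monitoring data require the real research database.
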