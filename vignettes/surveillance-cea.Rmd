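---
title: "A monthly-cycle micro-simulation for post-metastasectomy surveillance economics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A monthly-cycle micro-simulation for post-metastasectomy surveillance economics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasurv)
```

## The decision problem

After curative-intent resection of stage IV colorectal cancer metastases,
most patients eventually relapse, but recurrence detected while still
asymptomatic is far more often amenable to repeat curative-intent resection
than recurrence that declares itself through symptoms. Surveillance — clinic
visit, carcinoembryonic antigen (CEA) testing and CT at scheduled intervals,
plus up to two colonoscopies — buys earlier detection at the price of repeated
testing. `metasurv` implements a cost-utility model that quantifies that
trade-off for four schedules used in practice: visits every 12 months for 5
years (`q12`), every 6 months for 2 years then annually (`q6_q12`), every 6
months for 5 years (`q6`), and every 3 months for 2 years then annually
(`q3_q12`), with a no-surveillance comparator (`none`).

## Model structure

Patients move monthly through six states: no evidence of disease (NED),
undetected recurrence, curative-intent treatment, palliative treatment with
symptomatic disease, palliative treatment with asymptomatic
(surveillance-detected) disease, and death (absorbing). Within a cycle the
draw order is: death in the current state; recurrence (from NED); conversion
of undetected disease to symptomatic presentation; detection at a scheduled
visit; repeat resection given detection (probability 0.23 if asymptomatic,
0.05 if symptomatic); operative death given resection (0.010); and a
false-positive panel result at disease-free visits. Curative-intent treatment
(metastasectomy, recovery, and 6 months of perioperative chemotherapy)
returns the patient to NED with renewed recurrence risk, so repeat
resections and repeat detections are possible; palliative states exit only to
death. Symptomatic disease presents the cycle symptoms arise, independent of
the schedule — surveillance can only help through pre-symptomatic detection.

Mortality follows disease status, not awareness: the background hazard
applies in NED and during curative treatment, the post-recurrence hazard in
the undetected and both palliative states.

## Calibration: from printed summaries to monthly probabilities

Only point summaries of the source cohort are available, so each transition
is given a constant (exponential) hazard — the minimal assumption consistent
with a single survival point:

$$p_{\text{month}} = 1 - S(t)^{1/t}$$

* recurrence: cumulative incidence 75.1% by the 76.4-month median follow-up
  gives $p = 1 - 0.249^{1/76.4} \approx 0.01803$ per month;
* background death: 81.5% ten-year survival of non-recurred patients over
  120 months ($p \approx 0.00170$);
* post-recurrence death: 25.4% five-year survival of recurred patients over
  60 months ($p \approx 0.02258$).

The recurred stratum's 5- and 10-year survival (25.4%, 3.1%) are not jointly
consistent with one exponential; the 5-year point anchors the hazard because
it dominates the within-horizon dynamics, and the implied 10-year value
(6.5%) is reported by `parameter_recovery()` rather than hidden. The
undetected-to-symptomatic sojourn is geometric on whole cycles with mean 4
months ($p = 1/4$ per cycle), the discrete analogue of an exponential wait in
a cycle-based engine. No competing-risk or censoring correction is applied to
the 75.1% — the source provides no at-risk table — so the recurrence hazard
should be read as "cumulative incidence reproduced at the anchor time", which
`generate_cohort()`/`summarize_cohort()` verify by construction.

## Test panel and schedules

Tests at a visit are combined as conditionally independent given disease
status: panel sensitivity $1 - \prod_i (1 - \text{sens}_i) = 0.9645$ for
clinic + CEA + CT (0.9982 with colonoscopy), panel false-positive probability
$1 - \prod_i \text{spec}_i = 0.2049$. Visits sit at interval ends; the two
colonoscopies at months 12 and 48 coincide with scheduled visits; active
surveillance stops at month 60 while symptomatic presentation remains
possible to the 120-month horizon. A false-positive visit triggers one
confirmatory CT — a cost, no state change and no utility decrement — and this
charge can be switched off (`clinical$charge_false_positive_workup`). After
successful repeat curative treatment the patient resumes the original
calendar schedule; nothing restarts, which also caps colonoscopies at two per
trajectory.

## Utilities, costs and two deliberate conventions

Four published utilities map to five living states: NED 0.78; undetected
recurrence and curative treatment both carry the generic recurrence utility
0.74; asymptomatic palliative disease 0.68; symptomatic palliative disease
0.50. All are config-overridable.

Two costing decisions were genuinely open:

* **Perioperative chemotherapy.** No cost is published for the 6 months of
  curative-intent chemotherapy; `curative_chemo_month` defaults to the
  monthly palliative systemic-therapy cost (CAD 6409.77) as a proxy, charged
  for each of the 6 treatment cycles.
* **Palliative systemic therapy.** The published CAD 6409.77 does not state
  whether it covers a month or a course. Charged monthly for the remaining
  lifetime it implies mean 10-year costs two orders of magnitude above any
  published per-strategy surveillance cost level, so the package charges it
  as a single course cost at entry into a palliative state
  (`clinical$palliative_chemo_duration = 1` cycle). Setting the duration to
  the horizon recovers the per-month-for-life reading.

## Discounting and half-cycle correction

Costs and outcomes in cycle $c$ are discounted mid-cycle,
$(1 + r)^{-(c - 0.5)/12}$ with $r = 1.5\%$ per year. Death truncates a cycle:
state utility, life-years and continuous treatment costs take half weight in
the death cycle, while one-off event costs (visits, surgery) keep full
weight. Together these implement half-cycle correction at the individual
level.

## Random numbers and reproducibility

Every stochastic decision has a fixed address `(seed, patient, cycle,
purpose)` hashed through splitmix64 into a uniform draw. Consequences:

* identical seed and config give bit-identical results, across machines;
* two strategies simulated with the same seed share every draw both consume
  (common random numbers), so paired comparisons are sharp — with a blind
  test panel, an active schedule reproduces the no-surveillance QALY vector
  exactly;
* the per-cycle transition kernel exists twice — `step_patient()` in R and
  the compiled engine in C++ — sharing only the draw primitive, and the test
  suite asserts trajectory-level equality between them.

The PSA holds the simulation seed constant across parameter draws, so
draw-to-draw variation isolates parameter uncertainty and a point-mass PSA
collapses to the base case exactly.

## Probabilistic sensitivity analysis

Families follow the published table: gamma for costs with a usable spread and
for the time-to-symptomatic interval, beta for test characteristics and
operative mortality; utilities, resection rates and costs without a usable
spread stay fixed. Published ranges are read as 95% intervals
(SD = width/3.92); published SDs are used directly. Moments are matched
(gamma: shape $(m/s)^2$; beta: mean/variance), infeasible beta moments are
clamped or held fixed with a warning (colonoscopy specificity, mean 1.0), and
sampled time-to-symptomatic is floored at its 1-month plausibility bound.
That floor concentrates roughly half of the gamma's mass at exactly 1 month —
a direct consequence of moment-matching a mean-4, SD-6.9 distribution — and
materially shapes the acceptability curves: in such draws conversion always
precedes any visit, every schedule is outcome-identical, and the cheapest
strategy wins at any willingness-to-pay.

## Incremental analysis conventions

`incremental_table()` sorts by cost, marks absolute dominance (no more
costly, at least as effective, one inequality strict), then removes
strategies whose frontier ICER strictly exceeds the next survivor's
(extended dominance), keeping collinear ties. Two ICER columns are reported:
`icer` against the adjacent table row (the convention of published strategy
tables) and `frontier_icer` against the previous surviving strategy. An
independent brute-force oracle (`frontier_oracle()`, exhaustive
net-monetary-benefit search over all pairwise indifference thresholds) is
tested against the elimination loop on 1000 random instances.

## The synthetic cohort

`generate_cohort()` draws continuous exponential event times with the same
monthly hazards the engine uses (the engine's geometric cycle process is
exactly the ceiling of those times), so fixed-time summaries recover the
calibration inputs without discretization bias. Death clocks are independent
of detection: the generator emulates the *observed* cohort that produced the
summaries, it does not model treatment benefit — that is the engine's job.
It therefore cannot validate treatment-effect assumptions, only the
calibration identities and the detection/resection plumbing. Real registry
features it does not emulate: individual follow-up variation (one common
follow-up time is used), site-of-metastasis strata, loss to follow-up, and
non-cancer competing mortality.

## Problem sizes and numerical choices

The package's own test suite runs 10,000-patient base cases, a 500-draw ×
500-patient PSA, 2,000-patient DSA scenarios, and 50,000-patient cohort
recoveries; the compiled engine makes each of these a matter of seconds.
Monte Carlo checks use 3-standard-error bands. Ties in net monetary benefit
are split equally across strategies so acceptability probabilities sum to
one; dominance comparisons use exact arithmetic on means.

## Known limitations

* Constant hazards everywhere. With the recurrence hazard anchored at 76.4
  months, recurrences keep arriving throughout the 5-year surveillance
  window, so mid-period visits (months 30/42/54) retain real marginal
  detection value — which is why the `q6` schedule is *not* dominated in this
  model's base case. Reported dominance patterns for mid-intensity schedules
  are sensitive to the hazard shape (front-loaded recurrence would concentrate
  value in early visits) and to the palliative costing convention; neither is
  identifiable from point summaries.
* Detected asymptomatic palliative patients keep utility 0.68 until death
  (the state has no symptomatic transition), which credits detection with a
  durable quality-of-life benefit even without resection.
* No treatment toxicity, no molecular stratification, no life-table
  background mortality, and no lead-time refinement of detection within a
  cycle.
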