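# metasurv

Cost-utility micro-simulation of follow-up surveillance after curative-intent
metastasectomy of stage IV colorectal cancer.

Most patients relapse after metastatic resection, and recurrence caught while
asymptomatic is several times more likely to be treatable with repeat
curative-intent surgery than recurrence that presents with symptoms.
Surveillance programs — clinic visit, carcinoembryonic antigen (CEA) test and
CT at fixed intervals, plus colonoscopy at years 1 and 4 — buy earlier
detection at the cost of repeated testing. `metasurv` is for health-economics
and clinical-research audiences who want a fully reproducible, tested
implementation of that trade-off: which schedule intensity is worth paying
for, at what willingness-to-pay, and how sensitive the answer is to the
inputs.

## The model

A Markov micro-simulation with monthly cycles over a 10-year horizon. Six
health states: no evidence of disease (NED), undetected recurrence,
curative-intent treatment, palliative treatment with symptomatic disease,
palliative treatment with asymptomatic disease, dead. Transition
probabilities are calibrated from published cohort summaries by
constant-hazard conversion,

```
p_month = 1 - S(t)^(1/t)
```

giving a monthly recurrence probability of 0.0180 (75.1% cumulative
recurrence by 76.4 months), a background death probability of 0.0017 (81.5%
10-year survival without recurrence) and a post-recurrence death probability
of 0.0226 (25.4% 5-year survival after recurrence). Undetected disease
becomes symptomatic with probability 1/4 per month; detection at a visit uses
the panel sensitivity `1 - prod(1 - sens_i)` of the tests performed; repeat
resection follows detection with probability 0.23 (asymptomatic) or 0.05
(symptomatic). Costs (2021 CAD, public-payer) and utilities accrue per cycle
with mid-cycle discounting at 1.5%/year and half-cycle credit in the death
cycle. Downstream of the engine: dominance-annotated incremental
cost-effectiveness tables, probabilistic sensitivity analysis (gamma/beta
resampling), cost-effectiveness acceptability curves, and one-/two-way
deterministic sensitivity analyses. Four schedules are compared: `q12`,
`q6_q12`, `q6`, `q3_q12` (plus a `none` comparator).

## Worked example

```r
library(metasurv)
cfg <- default_config()          # packaged base case (also in inst/extdata/)
calibrate(cfg)
#> <metasurv_transitions> (per monthly cycle)
#>   p_recur_month                0.018033
#>   p_symptomatic_month          0.250000
#>   p_die_background_month       0.001703
#>   p_die_postrecurrence_month   0.022581
#>   ...

res <- run_strategies(cfg, n_patients = 10000, seed = 17)
incremental_table(res, effect = "qaly")
#>   strategy    cost effect delta_cost delta_effect  icer frontier_icer dominance
#> 1      q12  9508.4 4.2014         NA           NA    NA            NA reference
#> 2   q6_q12 10850.5 4.2523    1342.06     0.050965 26333         26333  frontier
#> 3       q6 11913.1 4.2870    1062.63     0.034682 30639         30639  frontier
#> 4   q3_q12 12798.5 4.2983     885.32     0.011317 78230         78230  frontier
```

Reading the table: strategies are ranked by mean discounted cost per patient;
`effect` is mean discounted QALYs; each `frontier_icer` is the extra cost per
extra QALY of stepping up to that schedule from the previous surviving one.
Here annual surveillance (`q12`) is the cheapest option, each intensification
adds QALYs (asymptomatic detections rise from 14% to 26% of patients), and
stepping all the way to `q3_q12` costs about CAD 78,000 per additional QALY —
so at a CAD 50,000/QALY threshold the deterministic base case stops short of
the most intensive schedule. Probabilistic uncertainty is handled separately:

```r
draws <- run_psa(cfg, n_draws = 500, n_patients = 500, seed = 17)
ceac(draws, cfg$settings$wtp_grid)   # acceptability curves; plot_ceac(...)
```

which shows `q12` with the highest probability of being cost-effective at
CAD 50,000/QALY. Deterministic scenario analyses
(`one_way_dsa()`, `resection_rate_dsa()`, `two_way_dsa()`) and a
synthetic-cohort parameter-recovery loop (`generate_cohort()` →
`summarize_cohort()` → `parameter_recovery()`) round out the analysis
surface; `cmd_run()`/`cmd_psa()`/`cmd_dsa()`/`cmd_cohort()` (and the script
in `inst/cli/`) write CSV results with a JSON run manifest.

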