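# bpimpact

Budget-impact modelling of hypertension guideline adoption: what does it
cost a national healthcare payer to move the diagnostic cut-off for high
blood pressure from 140/90 mmHg to the 2017 AHA/ACC threshold of
130/80 mmHg, with the correspondingly stricter treatment goal
(SBP < 120 mmHg instead of < 140 mmHg)?

The package is aimed at health economists and HTA analysts. It implements
a deterministic two-scenario cohort model over a three-year horizon
(2018–2020) plus a second-order Monte Carlo probabilistic sensitivity
analysis (PSA), with synthetic generators standing in for the national
data sources (population projections, age-specific prevalence tables,
administrative event-count series).

## The model

For each scenario *s* (baseline 140/90 vs new 130/80) and year *t*, the
prevalent hypertensive population `N_{s,t}` flows through a
prescription/adherence cascade:

```
treated    T = (N − N_new)·p_rx·a_old + N_new·p_rx·a_new
untreated  U = N − T
```

where `p_rx` is the physician prescription probability (0.52), `a_old`
the adherence of established hypertensives (0.45), `a_new` the adherence
of the stratum newly classified by the lower cut-off (0.2), and `N_new`
that stratum's size (the excess of the new scenario's prevalents over
the baseline's). Expected annual cardiovascular events are

```
E_k = T·p_k(regime) + U·p_k(untreated),   k ∈ {AMI, stroke, HF, CV death}
```

with the treated regime's probabilities taken from the intensive or
standard arm of the SPRINT trial and the untreated probabilities from
calibrated local sources. Annual costs are medication
(`T · tablets/day · USD/tablet-day · 365`), diagnostic aids
(`N · frequency · panel cost`) and complication management (episode
costs per event; each HF case incurs decompensation episodes plus one
year of chronic management). Treated survivors carry over into the next
year's prevalent pool. The budget impact is the difference in total
cost, new minus baseline; the PSA redraws every distribution-tagged
parameter (Beta for probabilities, Poisson for resource means, Gamma for
costs) once per iteration, shared between scenarios, and reports the
fraction of iterations in which the new guideline saves money.

## Worked example

```r
library(bpimpact)
params     <- load_parameters()   # packaged parameter table
projection <- generate_population(base_total = 33e6, annual_growth = 0.012)
baseline_rule <- list(type = "override", counts = c("2018" = 8675154))
new_rule      <- list(type = "override", counts = c("2018" = 13271577))
run_b <- run_scenario(baseline_scenario(params, baseline_rule), params, projection)
run_n <- run_scenario(new_scenario(params, new_rule, baseline_rule), params, projection)
budget_impact(run_b, run_n)
```

```
Budget impact (new - baseline), USD [nominal]
 year baseline_usd     new_usd difference_usd
 2018   5205793752  8296900837     3091107085
 2019   6602521268 10069684577     3467163309
 2020   6839832646 10347842764     3508010118
Horizon total: 10,066,280,512 (added cost)
```

Each row is one horizon year: the total medical-care cost of the
baseline (140/90) and new (130/80) scenarios and their difference, in
nominal USD; a negative difference would be a saving. Under the
package's default structural assumptions the wider guideline *adds*
cost, because the newly diagnosed-but-untreated stratum imports the high
calibrated untreated event probabilities — see the methods vignette
(`vignettes/budget-impact-methods.Rmd`) for why this structural choice
dominates the result and how to explore alternatives. The PSA
(`run_psa(params, scenarios, projection, n_iter = 5000, seed = 1)`)
propagates the parameter table's Beta/Poisson/Gamma uncertainty through
both scenarios and summarises the distribution of the difference.

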