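---
title: "Methods: a two-scenario budget-impact model for hypertension guideline adoption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-scenario budget-impact model for hypertension guideline adoption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpimpact)
```

## The question and the model

Lowering the diagnostic threshold for hypertension from 140/90 mmHg to
130/80 mmHg (with an intensive treatment goal of SBP < 120 mmHg) greatly
expands the diagnosed population. From a payer's perspective the question
is whether the extra spending on medication and diagnostic work-up is
offset by avoided cardiovascular complications. `bpimpact` answers it
with a deterministic cohort flow compared across two scenarios, plus a
second-order Monte Carlo PSA for parameter uncertainty.

Each scenario-year proceeds through four stages:

1. **Prevalence.** The prevalent hypertensive population comes from a
   configurable rule: a fixed overall rate applied to the over-20
   population, an age-weighted prevalence table, or an absolute count
   override (used when the prevalent populations are known directly, as
   for 2018). In the new scenario, the *newly classified stratum*
   (patients with BP 130–139/80–89 who were not hypertensive under the
   old definition) is the excess of the new scenario's prevalents over
   the baseline's.
2. **Cascade.** A fraction `p_rx = 0.52` of prevalents receives a
   guideline-conforming prescription; of those, 45% of established
   hypertensives and 20% of the newly classified stratum adhere.
   Adherent prescribed patients are "treated"; everyone else —
   unprescribed or non-adherent — is pooled as "untreated".
3. **Events.** Expected annual counts of AMI, stroke, heart failure and
   cardiovascular death are linear in the compartments: treated patients
   experience the standard-control probabilities in the baseline
   scenario and the intensive-control probabilities in the new scenario;
   untreated patients experience the calibrated untreated probabilities.
   Events are expected values, not draws — the model is deterministic
   given its parameters — and outcomes are independent (no competing
   risks; a patient can contribute to several outcome expectations in
   one year).
4. **Costs and carry-over.** Costs are medication (tablets/day × unit
   cost × 365 for treated patients), diagnostic aids (panel frequency ×
   panel cost for *all* diagnosed prevalents, treated or not) and
   complication management (episode costs; each incident HF case incurs
   its decompensation episodes plus one year of chronic management;
   deaths carry no direct cost). Treated patients who survive the year
   are added to the next year's prevalent pool before re-partitioning.

The budget impact is the per-year and horizon difference in total cost,
new minus baseline; negative values are savings.

## Parameters

The packaged fixture (`default_parameter_file()`) carries the full
parameter table: cascade probabilities, the twelve annual event
probabilities (standard/intensive/untreated × four outcomes), resource
means (1.8 and 2.8 tablets/day for standard and intensive control, 0.61
diagnostic panels/year, 2.2 HF decompensations/year), unit costs
(USD 0.00556 per tablet-day, USD 57.91 per diagnostic panel,
year-specific AMI episode costs of USD 2938/3235/2934, stroke USD 3430,
HF decompensation USD 1990, chronic HF USD 1131/year), and the globals:
baseline prevalence 7.2%, horizon 2018–2020, CPI growth rates
3.95/4.35/3.95%, an exchange rate of 2877 COP/USD, and 5000 PSA
iterations.

Each uncertain parameter carries a PSA distribution: Beta for
probabilities (shapes are event/non-event counts), Poisson for resource
means, Gamma for costs, with the Gamma distributions parameterised on
the COP scale (their implied means are COP-magnitude; draws are divided
by 2877 to give USD). The unlabelled currency of the diagnostic-panel
cost is taken as USD, consistent with its neighbouring rows.

Several rows are internally inconsistent: the printed point estimate
disagrees with the distribution's analytic mean (prescription 0.52 vs
Beta(29,31) → 0.483; panel frequency 0.61 vs Poisson λ = 1.5; HF
episodes 2.2 vs λ = 2; all three cost Gammas). `reconcile()` offers
three policies: keep both as printed (`point_estimate`), replace the
estimate by the distribution mean (`distribution_mean`), or — the PSA
default — rescale the distribution onto the printed estimate
(`rescaled_distribution`: Beta holds a+b and moves a; Poisson sets λ;
Gamma adjusts scale only). Deterministic runs always use point
estimates, because the source's deterministic results are stated in
point-estimate terms; which convention its authors actually used for the
inconsistent rows is unknowable, so neither is asserted.

## The PSA

Each iteration draws one value per distribution-tagged parameter and
runs both scenarios under the *same* draws (common random parameters;
independent draws would inflate the variance of the difference
unrealistically). Probabilities for the intensive and standard regimes
are drawn independently from their Beta distributions — no rank
correlation is imposed, matching the table's independent rows. Poisson
draws of resource means are integer by nature and are used directly as
population means, accepting the source's unusual choice of a Poisson for
a mean. Per-iteration substream seeds are derived deterministically from
one root seed, so the result is reproducible and invariant to iteration
order. The headline summary is the fraction of iterations with a
negative horizon cost difference, reported per year and pooled over the
horizon total (the pooled and per-year views can legitimately differ; both
are kept).

## Synthetic data

Three generators stand in for the national data sources, so the whole
pipeline is testable offline:

* `generate_population()` emulates a statistics-office projection:
  33 million adults over 20 in 2018 growing at 1.2%/year (a realistic
  magnitude for Colombia's adult population and growth), apportioned
  over decadal age bands 20–29 … 80+ by largest-remainder rounding so
  band counts conserve annual totals exactly.
* `generate_prevalence_table()` builds age-increasing prevalence tables
  for the two cut-offs whose population-weighted overall prevalences hit
  their targets exactly, the new cut-off dominating the old in every
  band.
* `generate_event_history()` produces noisy trending annual claim counts
  per ICD-10 code (I219 = AMI, I509 = HF, I64 = stroke) for the
  validation forecasts.

What the generators do **not** emulate: real age-specific prevalence
shapes, migration or mortality structure in the projection, coding
practice changes or reporting lags in claims series. Passing tests
therefore demonstrate the model's internal correctness and calibration
machinery, not agreement with real surveillance data.

The printed 2018 prevalent counts (8,675,154 baseline; 13,271,577 new —
a 53% increase) are supplied as per-scenario overrides rather than
derived, because no plausible over-20 population reproduces them from
the 7.2% baseline prevalence. Override years beyond 2018 scale the
latest supplied count by the projection's population growth.

## Numerical choices

* Compartment counts are integers (people). Products are rounded
  half-to-even at compartment boundaries, and the rounding residual is
  assigned to the untreated pool, so `treated + untreated =
  hypertensive` holds exactly in every scenario-year.
* Survivor carry-over attributes deaths to the treated compartment in
  proportion to its size (the attribution is otherwise unspecified), and
  carried survivors join the established stratum; everyone re-enters the
  prescription/adherence cascade each year. A negative carried pool is
  clamped to zero with a warning.
* Cost breakdowns are nominal per year. CPI deflation to 2018 real
  terms is applied only when aggregating horizon totals
  (`budget_impact(..., real_terms = TRUE)`); `deflate()` also exposes the
  inverse (inflation), since whether a given source deflated or inflated
  is often ambiguous.
* The untreated cardiovascular-death probability is absent from the
  parameter table; the default applies the standard-control value
  (0.0043) to untreated patients — conservative, and some value is
  needed because deaths drive the carry-over — overridable to zero.
* The exponential-smoothing validation forecast uses the level-only
  recursion `S_t = αy_t + (1−α)S_{t−1}` with α = 0.1, a flat point
  forecast, and a Gaussian 95% interval from the standard deviation of
  the one-step-ahead errors `y_t − S_{t−1}`. This is one standard SES
  interval construction; it is isolated in `ses_forecast()` so it can be
  swapped. External hazard-ratio reference intervals are always
  user-supplied, never hard-coded.

## Problem sizes

The model is desk-scale by construction: a full three-year two-scenario
run at national population size is milliseconds, and the default
5000-iteration PSA completes in well under a minute on one core. The
test suite and the acceptance script run everything at full size.

## Known limitations

The dominant structural sensitivity is **who bears the untreated event
probabilities**. The calibrated untreated probabilities are an order of
magnitude above the treated ones (e.g. 10.4%/year for stroke), and the
default design applies them to the entire untreated compartment —
including the newly classified stratum, whose members are untreated
mild hypertensives. Because the new scenario diagnoses ~4.6 million
additional people of whom only a fifth adhere to treatment, the wider
guideline *increases* the modelled event and cost burden under these
defaults: diagnosis effectively imports event risk into the model's
accounting that the baseline scenario never counts. The package's own
runs (see the README example and `scripts/acceptance.R`) show the
consequence: the deterministic budget impact is positive (an added cost)
and essentially no PSA iteration yields a saving. Users who believe the
newly classified stratum's untreated risk should be lower (or that
untreated risk should attach only to established, severe hypertension)
can express that by editing the parameter file's untreated probabilities
or the scenario's prevalence rules; the conclusion flips only through
such structural choices, not through any plausible variation of the
remaining parameters.

Also out of scope, deliberately: lifestyle-modification effects,
quality-of-life outcomes (no QALYs or ICERs), retinopathy, nephropathy
and peripheral-artery complications, rehabilitation and outpatient
follow-up costs, adverse events of intensive treatment, and sex/age
subgroup effect sizes. Chronic HF costs do not persist beyond the
incident year (a config hook exists). Competing risks are ignored.
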