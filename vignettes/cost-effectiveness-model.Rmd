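---
title: "A Markov cohort model of COMT-inhibitor cost-effectiveness in Parkinson's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of COMT-inhibitor cost-effectiveness in Parkinson's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkcem)
```

## The decision problem

Levodopa-treated people with Parkinson's disease develop end-of-dose motor
fluctuations: periods ("OFF-time") in which medication no longer controls
motor symptoms. Adjuvant COMT inhibitors extend levodopa's effect; the
question `parkcem` addresses is whether once-daily opicapone is
cost-effective against the six entacapone preparations prescribed in
England (stand-alone generic and branded-generic 200 mg entacapone, and
four levodopa/carbidopa/entacapone combination products), from an NHS and
personal social services perspective.

Patients are stratified at 25% of awake time spent OFF: spending less than
a quarter of the day OFF is associated with substantially better
health-related quality of life and lower healthcare costs, which is what
gives the comparison its economic structure.

## Model structure

The model is a Markov cohort state-transition model over three clinical
health states — <25% OFF-time, >=25% OFF-time, and dead. Internally each
alive state is split by treatment status, giving five compartments
(`compartment_names()`): discontinuation moves mass from the ON to the OFF
compartments and the split is what lets costing distinguish patients still
taking the COMT inhibitor from those who have stopped, while utilities
depend only on the OFF-time stratum.

The schedule is a 3-month first cycle (matching the pivotal trial's
duration), a 9-month second cycle, and annual cycles thereafter to a
25-year horizon (26 cycles). Costs are 2021/22 GBP; costs and QALYs are
discounted at 3.5% per year and compared at a threshold of GBP 20,000 per
QALY.

Within each cycle, events compose in a fixed order:

1. **Discontinuation** at the cycle start, in model years 2–6 only
   (year 1 compliance is 100%; patients on treatment at the end of year 6
   never discontinue). Discontinuing patients forfeit all treatment
   benefit: from <25% OFF-time they are redistributed at the baseline
   OFF-time split (9.5% remain <25%, 90.5% move to >=25%); from >=25%
   OFF-time they remain there while alive.
2. **Death**, at the life-table background probability for the cohort's
   age and sex mix, multiplied by a Parkinson's mortality hazard ratio of
   1.61 (capped at 1) and converted to the cycle length.
3. **OFF-time movement** among survivors. Cycle 1 applies the arm's
   treatment response (>=25% to <25%, the only cycle in which improvement
   is possible); cycles 2 onward apply natural decline from <25% to >=25%
   at an annual probability of 0.17 — the reciprocal of the 5.85-year gap
   between mean levodopa-treatment durations in the two strata
   (11.38 − 5.53 years) — converted to the cycle length.

The ordering (discontinue, then die, then move) is a modelling choice the
source text does not pin down; it is fixed, not configurable, so results
are reproducible, and the transition matrices are property-tested against
an exhaustive enumeration of this event tree.

### Probability conversions

All duration conversions (annual decline and mortality to 3-, 9-, and
12-month cycles; 3-month adverse-event probabilities to cycle lengths) use
the constant-rate transform `1 − (1 − p)^(t'/t)`. The hazard ratio is
applied multiplicatively to the annual death *probability* (with a cap at
1) rather than to the hazard, following the source model's wording; the
two differ at very old ages, which matters little over a horizon ending at
age 89.

## Costing

Four streams are costed per cycle and per compartment, charged to the
occupancy at cycle start (a who-pays-at-entry convention; a mid-cycle
option exists):

* **Pharmaceutical**: daily COMT-inhibitor tablets (pack price / pack
  size × daily doses) plus levodopa at the cycle's levodopa-equivalent
  daily dose (LEDD), priced per mg from the 100 mg × 100-tablet pack.
  Combination preparations already contain levodopa, so they cost tablets
  only — implemented literally, with no supplementation charged above the
  tablets' content. Entacapone arms take five 200 mg doses per day (the
  WHO defined daily dose of 1 g; the trial mean of 4.3 daily intakes,
  860 mg, rounds up to five whole tablets). Off-treatment patients pay
  levodopa only, at 847 mg/day by default — the entacapone-arm
  steady-state LEDD, on the argument that foregone benefit implies
  reversion to non-opicapone levodopa requirements.
* **Treatment-dependent resource use**: per-cycle neurology outpatient
  visits (priced at the consultant-led specialist rate of GBP 324.39, a
  40%/60% weighting of two consultant-led tariffs), other outpatient
  visits (GBP 164.17), and A&E attendances (GBP 242.03), identical across
  OFF-time states. The mapping of the neurology visit to the consultant-led
  rate is a choice: the tariff rows never name it, but the consultant-led
  row is otherwise unused and its service codes are neurology-adjacent.
  Off-treatment patients retain their arm's schedule by default (the
  source data cannot disentangle them); `options$off_treatment_hcru =
  "entacapone"` switches them to the stand-alone entacapone schedule.
* **OFF-time-dependent resource use**: annual hospital admissions (with
  length of stay), GP visits, and Parkinson's-nurse visits per stratum,
  scaled to the cycle length; the >=25% stratum is roughly three times as
  expensive, which drives the result.
* **Adverse events**: six event types costed by clinician-elicited
  management patterns (e.g. dyskinesias = 25% of a GP visit = GBP 10.50),
  accruing to on-treatment mass only.

QALYs attach 0.692 (<25% OFF) and 0.483 (>=25% OFF) per year to the
end-of-cycle occupancy by default; `options$half_cycle_correction`
averages start and end occupancy instead. Discount factors are evaluated
at each cycle's start time (`options$discount_timing = "midpoint"` uses
the midpoint); the source text states annual discounting but not its
within-year convention, and the default is the simplest one consistent
with it.

## Parameters and provenance

Everything printed in the source publication — unit costs, resource-use
schedules, LEDD, utilities, the hazard ratio, cohort and schedule
constants — ships as defaults flagged `"paper"` in
`config_provenance()`. Five groups of inputs only appear in its
supplementary material and are shipped as **placeholders** flagged
`"placeholder"`: cycle-1 response probabilities (0.25 opicapone, 0.20
entacapone), discontinuation schedules (years 2–6: 0.10/0.05×4 opicapone,
0.15/0.08×4 entacapone), 3-month adverse-event probabilities (0.05, except
dyskinesias 0.16/0.08), the PSA dispersions, and the off-treatment LEDD.
The placeholders honour the stated orderings (opicapone responds at least
as well, discontinues no more often; all entacapone preparations are
clinically identical) but are *not* the study's values, and absolute
results under them should be read accordingly: they reproduce the study's
qualitative findings (dominance everywhere, NMB largest against the
dearest preparation), not its exact pounds. All are overridable from a
JSON document via `load_config()`.

The bundled life table is a synthetic two-parameter Gompertz stand-in
(`generate_life_table()`): male `q(age) = 1 − exp(−3.5e−5 · e^{0.09·age})`,
female mortality 35% lower, calibrated by eye to the level and slope of
recent England & Wales period tables around retirement ages. A real table
supplied via `read_life_table()` takes precedence.

## Probabilistic sensitivity analysis

`run_psa()` re-runs the deterministic case on parameter sets drawn by
method-of-moments-fitted distributions: gamma for costs and resource use,
beta for probabilities and utilities, lognormal for the hazard ratio
(default sdlog chosen so the 95% interval spans ±25% of 1.61). Dispersion
defaults to a coefficient of variation of 20% — a common convention in
health-technology assessment, surfaced explicitly as an assumption in
`options$psa` since the study's variances are unpublished. Parameters are
sampled independently (no correlation structure is given); clinical and
resource-use draws are made once for stand-alone entacapone and copied to
every entacapone preparation, so within an iteration the entacapone arms
differ only by pack price, as in the source model. Each iteration derives
its own RNG stream from `(seed, iteration)`, so iterations are
order-independent. Invalid beta moment combinations fail at fit time
rather than being silently truncated. The default 2500 iterations match
the study; the per-comparator probability of cost-effectiveness is the
fraction of iterations with positive net monetary benefit at the
threshold.

Because Table-4-level percentages depend on the unpublished dispersions,
the package's tests assert ordering and convergence properties (the
probability is highest against the dearest comparator; fitted
distributions recover their moments; identical seeds give bit-identical
output), not the study's exact percentages.

## Scenario analyses

Four one-line overrides of the base case (`scenario_configs()`): starting
age 75 (the UK average for Parkinson's), entacapone at its 10-dose daily
maximum, entacapone at 4 doses, and hospital admissions shortened by 20%.
Under the defaults, opicapone remains dominant in all four.

## Verification strategy and numerical choices

* Transition matrices are checked row-stochastic to 1e−12 and against an
  independent event-tree enumeration over randomly generated parameter
  sets (`generate_random_config()`, which draws structurally valid
  configurations respecting all orderings).
* The cohort trace conserves mass to 1e−10 per boundary with
  monotonically non-decreasing death, and is validated against an
  individual-level microsimulation (`run_microsimulation_oracle()`) that
  pushes 100,000 individuals through the same matrices: cohort values must
  sit within three Monte-Carlo standard errors.
* With attrition switched off, occupancy follows the closed-form
  geometric decay `0.83^k` to 1e−12 and QALYs equal the geometric sum.
* The arithmetic behind every printed unit-cost derivation (consultant
  tariff weighting, adverse-event costs, dosing) is reproduced exactly at
  printed precision, and the published cost/QALY pairs fed through
  `compare_arms()` recover the published NMBs within the GBP 250 slack
  implied by 2-dp QALY rounding.

Problem sizes in the test suite — 100 random configurations for
conservation, 10 for microsimulation equivalence at n = 100,000, 2500 PSA
iterations — were chosen to exercise the properties at the study's own
scale while keeping a full run in minutes on one core.

Degenerate inputs are handled explicitly: a probability of 1 converted to
a shorter duration is an error (the rate is undefined); a hazard-ratio
product at or above 1 yields certain death within the cycle; zero-length
streams and empty results tables error rather than emitting misleading
output.

## Limitations

The model inherits the source study's structural limits: treatment affects
outcomes only through the 3-month first cycle; adverse events carry costs
but no disutility or state changes; there is no treatment sequencing after
discontinuation; and all comparisons are pairwise against opicapone rather
than a simultaneous efficiency frontier. Beyond those, this
implementation's placeholder clinical inputs and synthetic life table mean
its absolute costs and QALYs are illustrative: passing tests demonstrate
the engine's correctness and the robustness of the qualitative
conclusions under the documented assumptions, not agreement with the
study's supplementary-data-dependent absolute figures.
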