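# parkcem

A Markov cohort cost-effectiveness model of once-daily **opicapone**
versus six **entacapone** preparations (stand-alone generic and branded
generic, plus four levodopa/carbidopa/entacapone combination products) as
adjuvant therapy for levodopa-treated people with Parkinson's disease
experiencing end-of-dose motor fluctuations, from an NHS and personal
social services perspective.

It is written for health economists and modellers who want a tested,
fully configurable reimplementation of this decision problem: every
parameter is a field in a JSON-overridable configuration, every engine
step is a documented exported function, and the probabilistic and
scenario analyses are reproducible from seeds.

## The model

Patients occupy three health states — <25% OFF-time, >=25% OFF-time, dead
— with the alive states split internally by treatment status (five
compartments). The schedule is a 3-month cycle, a 9-month cycle, then
annual cycles to a 25-year horizon. Within a cycle, mass (i) discontinues
treatment in model years 2–6, forfeiting all benefit, (ii) dies at the
life-table probability q(age, sex mix) x HR 1.61, and (iii) moves between
OFF-time states: a cycle-1 treatment response r (>=25% → <25%), then
natural decline at 0.17/year = 1/(11.38 − 5.53), the reciprocal gap in
mean levodopa-treatment duration between strata. Costs (pharmaceutical,
treatment-dependent visits, OFF-time-dependent admissions/GP/nurse care,
adverse events) and utilities (0.692 / 0.483 per year) accrue per cycle,
discounted at 3.5%/year.

Arms are compared pairwise against opicapone by incremental cost
ΔC, incremental QALYs ΔE, dominance classification, and net monetary
benefit NMB = λ·ΔE − ΔC at λ = £20,000/QALY. The PSA redraws parameters
(gamma for costs/resource use, beta for probabilities/utilities,
lognormal for the hazard ratio; 2500 iterations) and reports the
probability of cost-effectiveness per comparator.

Inputs that are only published in the source study's supplementary
material (cycle-1 response, discontinuation, adverse-event rates, PSA
dispersions) ship as documented, overridable **placeholders** — see
`config_provenance()` and the vignette. Absolute results under the
defaults are therefore illustrative; the qualitative findings are what
the test suite pins down.

## Worked example

```r
library(parkcem)
cfg <- default_config()
det <- run_deterministic_case(cfg)
write_results_table(det, "base_case", "base_case.csv", cfg)
```

prints (costs to the nearest pound, QALYs to 2 dp):

```
                                                comparator cost_per_patient qalys_per_patient     icer   nmb
                                                 Opicapone           165596              6.15
                                        Entacapone generic           172426              6.11 Dominant  7776
                     Entacapone (branded generic, Comtess)           178414              6.11 Dominant 13764
                     Levodopa/carbidopa/entacapone generic           171993              6.11 Dominant  7343
  Levodopa/carbidopa/entacapone (branded generic, Stalevo)           178509              6.11 Dominant 13860
 Levodopa/carbidopa/entacapone (branded generic, Sastravi)           172806              6.11 Dominant  8157
   Levodopa/carbidopa/entacapone (branded generic, Stanek)           172804              6.11 Dominant  8155
```

Opicapone accrues fewer costs and more QALYs than every entacapone
preparation — "Dominant" in the ICER column — with the largest net
monetary benefit against the dearest preparation (Stalevo). Opicapone's
own pharmaceutical costs are mid-pack; the saving comes from lower
OFF-time-dependent state costs (more time spent below 25% OFF-time) and
lower treatment-dependent visit use.

The analysis drivers under `analysis/` run the full workflow and write
tables under `results/`:

```sh
Rscript analysis/01_base_case.R   # deterministic base case + cohort trace
Rscript analysis/02_scenarios.R   # four scenario analyses
Rscript analysis/03_psa.R [seed]  # 2500-iteration PSA + CEAC draws
```

A scenario is a one-line override, e.g.
`load_config('{"cohort": {"start_age": 75}}')`; see
`inst/extdata/example_overrides.json` and `scenario_configs()`.

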