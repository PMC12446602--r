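Package: parkcem
Title: Markov Cohort Cost-Effectiveness Model of COMT Inhibitors in
    Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition model evaluating the
    cost-effectiveness of once-daily opicapone against six entacapone
    preparations as adjuvant therapy to levodopa in Parkinson's disease
    patients with end-of-dose motor fluctuations, from an NHS and personal
    social services perspective. Health states stratify patients at 25% of
    awake OFF-time; the engine combines a cycle-1 treatment response,
    natural disease progression, expert-elicited discontinuation, life-table
    background mortality under a Parkinson's hazard ratio, and four costing
    streams (pharmaceutical, treatment-dependent resource use,
    OFF-time-dependent resource use, adverse-event management). Provides the
    deterministic base case (costs, QALYs, ICER/dominance, net monetary
    benefit), probabilistic sensitivity analysis with gamma/beta/lognormal
    parameter distributions and cost-effectiveness acceptability output,
    scenario analyses, an individual-level microsimulation oracle, and
    synthetic life-table and parameter-set generators for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
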