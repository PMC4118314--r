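# osteosim

A discrete event microsimulation of osteoporotic fractures and their
costs over the remaining lifetime of postmenopausal women.

Each woman is simulated individually in yearly intervals from age 50 (or
a configurable start age) to death or age 100. In every interval she can
develop postmenopausal osteoporosis, sustain fractures of six types
(hip, other femur, clinical vertebral, humerus, pelvis, wrist), be
hospitalized and rehabilitated, enter a nursing home — triggered by a
fracture or by background reasons — and die. Fracture hazards depend on
age, osteoporosis status (calibrated from the bone-mineral-density
gradient of risk per standard deviation of T-score), fracture history,
and residence; mortality depends on age, residence, and time since
fracture.

Costs accrue in a per-person ledger across sectors — hospital,
rehabilitation, long-term care, outpatient treatment, professional home
care, informal care, and productivity losses under both the
human-capital and the friction-cost approach — and are discounted at 3%
per year to the 2009 base year. Long-term care is attributed to
osteoporosis only up to the year a parallel counterfactual track says
the woman would have entered a nursing home anyway.

The headline quantity is the **lifetime cost attributable to
osteoporosis**: the paired difference between an average-risk cohort and
a counterfactual never-osteoporosis cohort simulated with common random
numbers, so the difference carries no between-group Monte Carlo noise.

## Worked example

```r
library(osteosim)
params <- default_parameters()
base <- run_base_case(params, n = 20000, seed = 42)
base
```

```
<cohort_summary> n = 20000 per risk group, seed = 42

Lifetime fracture counts per woman:
      fracture_type average_risk never_osteoporosis excess attribution_pct
                hip        0.271              0.143  0.129            47.4
        other_femur        0.028              0.013  0.015            52.7
 clinical_vertebral        0.170              0.118  0.052            30.6
            humerus        0.132              0.089  0.043            32.3
             pelvis        0.086              0.065  0.021            24.8
              wrist        0.221              0.188  0.034            15.2

Discounted direct lifetime costs per woman (EUR):
  average risk     4556
  never osteo      2824
  excess           1732 (38.0% of average)
```

Per-sector breakdown of the same run:

```r
out <- base$sectors[, c("sector", "average_discounted", "excess_discounted")]
out[, 2:3] <- round(out[, 2:3])
print(out, row.names = FALSE)
```

```
           sector average_discounted excess_discounted
         hospital               1707               659
   rehabilitation                195                80
   long_term_care               1546               609
       outpatient                168                37
        home_care                423               156
    informal_care                518               190
 productivity_hca                391                70
 productivity_fca                318                47
```

(The two productivity rows are alternative costing approaches for the
same losses and are never summed; `direct` totals cover the six direct
sectors only.)

Other entry points:

* `run_scenarios(params)` — 18 start populations crossing age (50/60/…),
  residence, osteoporosis status, and fracture history.
* `run_sensitivity(params)` — 20 one-way deterministic analyses
  (discount rates, switched mortality/costing assumptions, ±30%
  parameter shifts).
* `run_psa(params, m, n)` — probabilistic sensitivity analysis over
  beta/gamma/lognormal parameter distributions.
* `internal_validation(params, n)` — modeled versus input age-specific
  incidence and lifetime fracture-count distributions.
* `simulate_individual()` / `person_ledger()` — single-woman event
  histories and their full cost ledger, for inspection.

A thin command-line wrapper is installed as `exec/osteosim`
(subcommands `run`, `scenario`, `sensitivity`, `psa`, `validate`,
`write-defaults`), writing CSV results plus a JSON manifest.

## Parameters

All inputs ship as editable CSV tables under
`system.file("extdata", "parameters", package = "osteosim")`; use
`write_default_tables()` / `read_parameter_tables()` /
`build_parameter_set()` to export, edit, and reload them. Every row has
a `source` field, and `placeholder_manifest()` lists the rows whose
default values are documented guesses rather than wired-in evidence.
Derived quantities (subgroup relative risks, onset probabilities, the
previous-fracture prevalence ladder) are recomputed from their parents
on load. The vignette (`vignettes/osteosim-methods.Rmd`) documents the
model structure, every calibration formula, and the known consequences
of the placeholder inputs.

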