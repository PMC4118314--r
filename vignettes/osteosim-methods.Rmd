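---
title: "Model structure, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteosim)
```

osteosim is a time-driven discrete event microsimulation of osteoporotic
fractures over the remaining lifetime of postmenopausal women. This
vignette documents the model structure, the parameter tables it ships
with, the calibration formulas that turn published-style summary inputs
into the subgroup-specific quantities the simulation needs, and the
numerical conventions the implementation commits to. The worked examples
use small populations so the vignette stays cheap to build; the
experiment drivers default to study-scale populations.

## 1. Model structure

Each woman is simulated individually in yearly intervals from a start age
(50 by default, configurable up to 99) until death or the end of the
interval in which she turns 100 — at most 50 intervals. Her state
comprises:

* **age** and calendar model year (base year 2009 at simulation start);
* **osteoporosis status** (postmenopausal osteoporosis, irreversible);
* **fracture history**: the years of every fracture of six types — hip,
  other femoral, clinical vertebral, humerus, pelvis, wrist;
* **residence**: community or nursing home, and whether a nursing-home
  entry was caused by a fracture or by background (non-fracture) reasons;
* a parallel **counterfactual background track** recording when she would
  have entered a nursing home had she never fractured (section 4).

Within one yearly interval, events are evaluated in a fixed order:

1. **Osteoporosis onset.** A yearly onset probability per age class,
   derived from age-specific prevalence (section 3.4). Onset in the
   current year already affects this year's fracture probabilities.
2. **Fractures**, one Bernoulli draw per type. The probability is the
   general-population probability for the age class, multiplied by the
   relative risks for the woman's osteoporosis status, fracture history,
   and residence (section 3).
3. **Hospitalization and rehabilitation** draws for each incident
   fracture, using type-specific proportions (hip is always
   hospitalized).
4. **Nursing-home entry.** An incident fracture can trigger entry with a
   type- and age-specific admission probability; when several fracture
   types occur in the same interval, the highest admission probability
   among them is applied once. Community dwellers additionally face a
   background entry probability per age class.
5. **Counterfactual background entry** for the parallel track
   (section 4).
6. **Survival.** The all-cause death probability for her current age is
   multiplied by a residence relative risk and by a fracture-history
   relative risk (section 3.5). Fractures of the current interval count:
   a woman can fracture, accrue costs, and die within the same year.

Events fire when the uniform draw `u` satisfies `u <= p`, and all draws
come from deterministic counter-based streams (section 6).

## 2. Start populations and preloading

`scenario_spec()` describes a start population by age, residence
(community / nursing home), disease status (average osteoporosis risk at
the age-specific prevalence, currently osteoporotic, never osteoporotic),
and fracture history (prevalence-drawn, with previous fracture, without).
`preload_state()` initializes each woman accordingly; prevalence-drawn
characteristics use dedicated preload streams so that scenario variants
stay comparable under common random numbers. Eighteen combinations form
the standard scenario grid (`all_scenarios()`); nursing-home start
populations are only generated at ages where residence is plausible.

```{r scenarios}
all_scenarios()[["75_N_O_P"]]
```

## 3. Fracture and mortality risk calibration

The shipped inputs are population-level summaries: general-population
fracture probabilities by age class and type, an overall relative risk
for women with a previous fracture, a bone-mineral-density (BMD) gradient
of risk per standard deviation, mean T-scores by age, and residence
relative risks. The simulation needs *subgroup-specific* probabilities
that stay consistent with the population averages. Four closed-form
calibrations provide them; each is exported and unit-tested against an
independent oracle.

### 3.1 Previous fracture

Given the relative risk `rr` of women with a prior fracture versus those
without, and the prevalence `prev` of prior fracture in an age class, the
relative risk of the *fracture-free* subgroup versus the population
average is

```{r rr-noprev}
rr_no_previous_fracture(1.86, 0.25)
```

so that `prev * rr * rr_np + (1 - prev) * rr_np = 1` exactly. Hip
fractures use a hip-specific (higher) relative risk.

### 3.2 Osteoporosis via the BMD gradient of risk

T-scores are modeled as normal with mean `m` (age-specific) and unit
standard deviation; osteoporosis is T < -2.5, and fracture hazard scales
as `g^-(T - m)` with gradient `g` per standard deviation. The mean
relative hazard of the osteoporotic subgroup versus the population
average then has the closed form implemented in `rr_osteoporotic()`:

```{r rr-ost}
rr_osteoporotic(2.6, -1.5)
```

The complementary non-osteoporotic relative risk again follows from the
mixing identity, `rr_non_osteoporotic()`, which also guards against
inconsistent inputs (`prev * rr_ost > 1`).

### 3.3 Residence

Nursing-home residents carry type-specific fracture relative risks. The
community relative risk is derived from the population share living in
nursing homes so the population mix averages to one. The shipped share is
a single scalar; section 7 discusses the consequences.

### 3.4 Prevalence-to-incidence conversion

Irreversible states (osteoporosis; the counterfactual background
nursing-home track) ship as prevalence by age class. Assuming a constant
yearly onset probability `q` within each five-year class and no
differential mortality, `q` solves
`1 - (1 - p_lo) * (1 - q)^5 = p_hi`:

```{r prev-to-inc}
prevalence_to_incidence(0.044, 0.089, 5)
```

The previous-fracture prevalence ladder is itself derived from the
model's own probabilities by a fixed-point iteration (starting from the
share with a prior fracture at age 50), so that the preloaded history
prevalence and the history relative-risk calibration are mutually
consistent.

### 3.5 Mortality

The all-cause life-table probability is multiplied by a residence
relative risk and a fracture relative risk. Fracture excess mortality
depends on the type and the time since fracture in three bands (first
year, years 2–5, years 6–10; none beyond 10 years; wrist carries none).
When several fractures are in the window, the *highest* relative risk
applies — excess risks do not multiply. Deaths in the first year after a
hip or other femoral fracture before age 65 are treated as
fracture-attributable for productivity costing.

## 4. Cost accounting

Costs accrue in a per-person ledger with one row per (year, sector,
fracture type) and are discounted at 3% per year to 2009
(`amount / 1.03^(t - 1)`).

* **Acute sectors.** Hospitalized fractures book hospital and (when
  drawn) rehabilitation unit costs; non-hospitalized fractures book an
  outpatient treatment cost. Community dwellers aged 66+ additionally
  book professional home care and informal care for the fracture year
  with age-independent type-specific amounts; nursing-home residents do
  not.
* **Long-term care.** When a fracture causes nursing-home entry, the
  yearly nursing-home cost is attributed to osteoporosis from the entry
  year (half-weighted, a half-cycle correction for mid-year entry) until
  the year the parallel counterfactual track would have entered anyway —
  from that year on, care is considered background and no longer
  fracture-attributable. Without counterfactual entry, attribution runs
  to death.
* **Productivity.** Morbidity losses price type-specific lost work days
  at age-specific employment rates and a daily wage growing 2% per year.
  Mortality losses for fracture-attributable deaths before 65 book the
  lost earnings stream to retirement. Both are computed under the
  human-capital approach and the friction-cost approach (losses capped at
  the friction period); the two are reported as separate sectors, never
  summed.

`person_cost_totals()` is tested to equal the ledger sum exactly, per
person — every euro that enters a summary is traceable to a ledger row.

```{r ledger}
p <- default_parameters()
h <- simulate_individual(scenario_spec(50, "C", "avO", "prevalence"),
                         p, seed = 4, person_index = 9)
person_cost_totals(h, p)["discounted", ]
```

## 5. Attributable-cost estimation

The quantity of interest is the lifetime cost attributable to
osteoporosis: the paired difference between an average-risk cohort and a
counterfactual never-osteoporosis cohort. `run_base_case()` simulates
both groups with identical random streams (common random numbers), so
the difference is free of between-group Monte Carlo noise; with the
gradient of risk set to 1 the excess is *exactly* zero, which is one of
the package's acceptance tests.

```{r base-case}
run_base_case(p, n = 400, seed = 11)
```

On top sit `run_scenarios()` (the 18 start-characteristic populations),
`run_sensitivity()` (20 one-way deterministic analyses `S1`–`S20`:
discount-rate variants, switched mortality/costing assumptions, ±30%
parameter shifts), and `run_psa()` (probabilistic sensitivity analysis
drawing probabilities from moment-matched beta, costs from gamma, and
relative risks from lognormal distributions — from reported 95%
confidence intervals where shipped, else a default coefficient of
variation). `internal_validation()` compares modeled age-specific
incidence with the input tables and reports lifetime fracture-count
distributions.

## 6. Numerical conventions

* **Counter-based random streams.** Every decision in year `t` for
  person `i` uses draw `i` of a stream keyed by `(seed, year, slot)`,
  with one slot per decision type (onset; six fracture types;
  hospitalization; rehabilitation; nursing-home entry; background entry;
  counterfactual entry; survival). Adding a person or switching a
  scenario flag never shifts anyone else's draws, which is what makes
  paired designs exact. The global `.Random.seed` is saved and restored
  around every internal draw.
* **Dual implementation.** `simulate_individual()` is a deliberately
  plain per-person reference engine; `simulate_cohort()` is a vectorized
  implementation used by the experiment drivers. The two are tested to
  agree *exactly*, per person, on event histories, death ages, and cost
  matrices.
* **Yearly bookkeeping.** Fracture-history mortality bands are evaluated
  on whole-year offsets; the 6–10-year band is carried in a rolling
  10-year window in the vectorized path.
* **Half-cycle corrections** apply where a mid-year change matters:
  attributed long-term care in the entry year, and the first year of a
  lost-earnings stream.

## 7. Parameter provenance and placeholders

All inputs ship as plain CSV tables in
`system.file("extdata", "parameters", package = "osteosim")` and can be
exported, edited, and re-read:

```{r tables}
list.files(system.file("extdata", "parameters", package = "osteosim"))
```

Each table row carries a `source` field. Rows marked `placeholder` are
structurally required inputs for which no authoritative value is wired
in; their defaults are round, documented guesses (for example the
nursing-home population share of 5% and the background admission
prevalence ladder). `placeholder_manifest()` lists them so a user can
see at a glance which results rest on placeholder ground. Quantities
*derived* from other inputs (the previous-fracture prevalence ladder,
the community residence relative risks, onset probabilities) are
recomputed by `finalize_parameter_set()` rather than stored, so edits to
their parents propagate.

```{r manifest}
head(placeholder_manifest(default_parameters()))
```

**Known consequence.** Internal validation reproduces the input hip
incidence closely at younger ages but runs above it at high ages
(roughly +15–20% at 80–84 under defaults). This is structural, not
stochastic: the marginal calibrations of sections 3.1–3.3 hold per age
class for the *input* prevalences, while the simulated population drifts
from them — survivors accumulate fracture histories faster than the
placeholder ladders assume, the simulated nursing-home share exceeds the
placeholder 5%, and osteoporosis and fracture history are positively
correlated in the simulation but calibrated as if independent. The
acceptance suite measures this gap rather than hiding it; tightening it
would require empirical residence and history data, not code changes.

## 8. Limitations

* Yearly intervals: at most one fracture per type per year, and
  within-year event ordering is a modeling commitment.
* Calibrations hold per age class at the input prevalences; simulated
  subgroup mixes drift with survival and history accumulation
  (section 7).
* Unit costs are single-year 2009-style amounts; no cost inflation
  beyond the wage-growth assumption in productivity losses.
* No treatment, screening, or intervention layer: the model quantifies
  burden, not policy effects.
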