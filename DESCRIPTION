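Package: osteosim
Title: Discrete Event Microsimulation of Osteoporotic Fractures in
    Postmenopausal Women
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A time-driven discrete event simulation of osteoporotic
    fractures (hip, other femur, clinical vertebral, humerus, pelvis,
    wrist) over the remaining lifetime of postmenopausal women. Each
    woman is simulated in yearly intervals from a configurable start age
    to death or age 100, with fracture hazards depending on age,
    osteoporosis status (calibrated from the bone-mineral-density
    gradient of risk), fracture history, and nursing-home residence.
    The package tracks multi-sector costs (hospital, rehabilitation,
    fracture-attributable long-term care via a parallel counterfactual
    nursing-home track, outpatient, professional home care, informal
    care, and productivity losses under the human-capital and
    friction-cost approaches), discounts them to a base year, and
    estimates osteoporosis-attributable excess costs by pairing risk
    groups with common random numbers. Experiment drivers cover the base
    case, start-characteristic scenarios, deterministic one-way
    sensitivity analyses, probabilistic sensitivity analysis, and
    internal validation against the input incidence tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
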