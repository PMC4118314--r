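# Shared helpers for the test suite.

# Default parameters, loaded once per test run.
default_params_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_parameters()
    cache
  }
})

# A parameter set with every subgroup relative risk neutralized (risk-factor
# effects off), optionally with mortality switched off entirely. In this
# homogeneous world every woman faces exactly the general-population
# fracture probabilities, which gives closed-form expectations.
neutral_params <- function(zero_mortality = FALSE) {
  raw <- default_params_cached()$raw
  raw$gradient[] <- 1
  raw$grad_lo[] <- 1
  raw$grad_hi[] <- 1
  raw$prevfx$rr_any <- 1
  raw$prevfx$rr_hip <- 1
  raw$prevfx$rr_osteo <- 1
  raw$rr_fx_nh[] <- 1
  raw$rr_fx_comm[] <- 1
  raw$rr_mort_nh <- 1
  raw$rr_mort_comm <- 1
  raw$mort_rr[] <- 1
  if (zero_mortality) raw$q_all[] <- 0
  finalize_parameter_set(raw)
}

# A fully specified woman_state for unit tests of single engine operations.
make_state <- function(age = 70, t = age - 49L, residence = "community",
                       osteoporotic = FALSE, has_prev = FALSE,
                       fx_years = NULL) {
  fx <- stats::setNames(rep(list(integer()), 6), fracture_types())
  if (!is.null(fx_years)) fx[names(fx_years)] <- fx_years
  state <- list(
    person_index = 1L, start_age = 50L, age = as.integer(age),
    t = as.integer(t), alive = TRUE, risk_group = "average_risk",
    osteoporotic = osteoporotic, has_prev = has_prev, fx_years = fx,
    residence = residence,
    residence_cause = if (residence == "nursing_home") "background"
                      else "none",
    nh_entry_year = NA_integer_, bg_cf_entered = FALSE,
    bg_cf_year = NA_integer_
  )
  class(state) <- "woman_state"
  state
}
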