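# Test-support generators: randomized-but-valid parameter sets for
# property-style tests and a small catalogue of degenerate "toy worlds" with
# closed-form expectations.

#' Generate a random, valid parameter set
#'
#' Jitters the default inputs multiplicatively (probabilities kept in
#' \[0, 1\], gradients kept >= 1, structural constraints such as the 100%
#' hospitalization of femoral fractures and the unit wrist mortality
#' multiplier preserved) and rebuilds the derived calibrations, so every
#' generated set satisfies all parameter-set invariants by construction.
#'
#' @param seed Seed for the jitter.
#' @param jitter Half-width of the multiplicative perturbation (default
#'   0.25: factors in \[0.75, 1.25\]).
#' @return A `parameter_set`.
#' @export
random_valid_parameters <- function(seed, jitter = 0.25) {
  params <- default_parameters()
  raw <- params$raw
  local_seed(seed, {
    jf <- function(k) stats::runif(k, 1 - jitter, 1 + jitter)
    raw$p_general[] <- pmin(raw$p_general * jf(60), 1)
    raw$rehab_prob[] <- pmin(raw$rehab_prob * jf(6), 1)
    raw$hosp_prob[] <- ifelse(raw$hosp_prob == 1, 1,
                              pmin(raw$hosp_prob * jf(6), 1))
    raw$gradient[] <- pmax(raw$gradient * jf(60), 1)
    raw$tscore[] <- raw$tscore + stats::runif(10, -0.2, 0.2)
    raw$prevfx$rr_any <- max(raw$prevfx$rr_any * jf(1), 1)
    raw$prevfx$rr_hip <- max(raw$prevfx$rr_hip * jf(1), 1)
    raw$prevfx$rr_osteo <- max(raw$prevfx$rr_osteo * jf(1), 1)
    raw$prevfx$prevalence[] <- pmin(raw$prevfx$prevalence * jf(10), 0.95)
    raw$nh_admission[] <- pmin(raw$nh_admission * jf(60), 1)
    raw$care_prev[] <- pmin(raw$care_prev * jf(10), 0.95)
    uc <- raw$unit_costs
    uc[!is.na(uc)] <- uc[!is.na(uc)] * jf(sum(!is.na(uc)))
    raw$unit_costs <- uc
    raw$ltc_yearly <- raw$ltc_yearly * jf(1)
    raw$mort_rr[] <- pmax(raw$mort_rr * jf(180), 1)
    raw$mort_rr[, "wrist", ] <- 1
    raw$q_all[] <- pmin(raw$q_all * jf(51), 1)
  })
  finalize_parameter_set(raw)
}

#' Degenerate toy worlds with closed-form expectations
#'
#' A fixed catalogue of parameter sets stripped down far enough that the
#' expected model output can be written down analytically:
#'
#' * `"no_mortality_flat_hazard"`: only hip fractures, a flat annual
#'   probability of 0.01, all relative risks 1, no mortality, no
#'   nursing-home dynamics. Expected lifetime hip count from age 50 is
#'   `50 * 0.01 = 0.5`.
#' * `"certain_death_year1"`: certain death in the first interval; expected
#'   lifetime costs are the first interval's costs only.
#' * `"nh_attribution_walkthrough"`: a hand-built person history with
#'   fracture-related nursing-home entry in model year 5, counterfactual
#'   background entry in year 8 and death in year 10; attributed long-term
#'   care is `2.5 * 25759 = 64397.5` (half-cycle on the entry year,
#'   attribution stops at the counterfactual entry).
#'
#' @param name Catalogue entry name.
#' @return List with `params`, `expected`, and for the walkthrough a
#'   `history`.
#' @export
toy_world <- function(name = c("no_mortality_flat_hazard",
                               "certain_death_year1",
                               "nh_attribution_walkthrough")) {
  name <- match.arg(name)
  params <- default_parameters()
  raw <- params$raw

  neutralize <- function(raw) {
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
    raw$nh_admission[] <- 0
    raw$care_prev[] <- 0
    raw
  }

  if (name == "no_mortality_flat_hazard") {
    raw <- neutralize(raw)
    raw$p_general[] <- 0
    raw$p_general[, "hip"] <- 0.01
    raw$q_all[] <- 0
    return(list(params = finalize_parameter_set(raw),
                expected = list(lifetime_hip = 0.5)))
  }

  if (name == "certain_death_year1") {
    raw <- neutralize(raw)
    raw$q_all[] <- 1
    return(list(params = finalize_parameter_set(raw),
                expected = list(n_intervals = 1L)))
  }

  # nh_attribution_walkthrough: synthetic history exercising the parallel
  # background track
  params <- finalize_parameter_set(raw)
  scen <- scenario_spec(50, "C", "avO", "nP")
  recs <- data.frame(t = 1:10, age = 50:59,
                     model_year = as.integer(raw$base_year) + 0:9,
                     osteo_onset = FALSE, nh_entry = "none",
                     bg_cf_entry = FALSE, died = c(rep(FALSE, 9), TRUE),
                     stringsAsFactors = FALSE)
  for (f in fracture_types()) {
    recs[[paste0("fx_", f)]] <- FALSE
    recs[[paste0("hosp_", f)]] <- FALSE
    recs[[paste0("rehab_", f)]] <- FALSE
  }
  recs$fx_hip[5] <- TRUE
  recs$hosp_hip[5] <- TRUE
  recs$nh_entry[5] <- "fracture"
  recs$bg_cf_entry[8] <- TRUE
  state <- list(person_index = 1L, start_age = 50L, age = 59L, t = 11L,
                alive = FALSE, risk_group = "average_risk",
                osteoporotic = FALSE, has_prev = TRUE,
                fx_years = stats::setNames(
                  c(list(5L), rep(list(integer()), 5)), fracture_types()),
                residence = "nursing_home", residence_cause = "fracture",
                nh_entry_year = 5L, bg_cf_entered = TRUE, bg_cf_year = 8L)
  class(state) <- "woman_state"
  history <- list(scenario = scen, person_index = 1L, seed = 0L,
                  records = recs, final_state = state)
  class(history) <- "person_history"
  list(params = params, history = history,
       expected = list(ltc_attributed = 2.5 * raw$ltc_yearly))
}
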