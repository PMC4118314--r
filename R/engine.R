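# Per-woman reference engine.
#
# This is the readable, operation-by-operation implementation of the yearly
# simulation loop: preload, fracture / hospitalization / rehabilitation
# draws, nursing-home entry, the counterfactual background track, and
# survival. simulate_cohort() re-implements the identical rules in vectorized
# form for large runs; a test suite enforces exact per-person agreement
# between the two paths under the shared CRN draw scheme.

#' Initialize a woman's state from a scenario (preload)
#'
#' Sets the start attributes: osteoporosis status (forced by `O`/`nO`, drawn
#' from the age-specific prevalence for `avO`), the previous-fracture flag
#' (forced by `P`/`nP`, drawn from prevalence otherwise), and residence. A
#' preloaded previous fracture carries the fracture-history risk multipliers
#' but no acute costs and no excess mortality: it happened before model start.
#'
#' @param scenario A [scenario_spec()].
#' @param params A `parameter_set`.
#' @param seed Master seed.
#' @param person_index Person index (determines the CRN substream).
#' @return A `woman_state` list.
#' @export
preload_state <- function(scenario, params, seed, person_index = 1L) {
  k <- age_class_index(scenario$start_age)
  osteo <- switch(scenario$disease,
    O = TRUE,
    nO = FALSE,
    avO = crn_uniform1(seed, person_index, 0L, SLOT_PRELOAD_OSTEO) <=
      params$ost_prevalence[k]
  )
  prev <- switch(scenario$history,
    P = TRUE,
    nP = FALSE,
    prevalence = crn_uniform1(seed, person_index, 0L, SLOT_PRELOAD_PREVFX) <=
      params$raw$prevfx$prevalence[k]
  )
  state <- list(
    person_index = as.integer(person_index),
    start_age = scenario$start_age,
    age = scenario$start_age,
    t = 1L,
    alive = TRUE,
    risk_group = if (scenario$disease == "nO") "never_osteoporosis"
                 else "average_risk",
    osteoporotic = osteo,
    has_prev = prev,
    fx_years = stats::setNames(rep(list(integer()), 6), fracture_types()),
    residence = if (scenario$residence == "N") "nursing_home" else "community",
    residence_cause = if (scenario$residence == "N") "background" else "none",
    nh_entry_year = if (scenario$residence == "N") 0L else NA_integer_,
    bg_cf_entered = FALSE,
    bg_cf_year = NA_integer_
  )
  class(state) <- "woman_state"
  state
}

#' Annual fracture probabilities for a woman's current state
#'
#' Combines the general-population probability with the multiplicative risk
#' adjustments for osteoporosis status, fracture history, and residence, plus
#' any secular trend factor, clipped to \[0, 1\].
#'
#' @param state A `woman_state` (must be alive).
#' @param params A `parameter_set`.
#' @return Named numeric vector, one annual probability per fracture type.
#' @export
annual_fracture_probabilities <- function(state, params) {
  if (!state$alive) stop("state must be alive")
  k <- age_class_index(state$age)
  rr_ost <- if (state$osteoporotic) params$rr_ost[k, ] else params$rr_noost[k, ]
  rr_hist <- params$rr_noprev[k] *
    (if (state$has_prev) params$rr_prev_type else rep(1, 6))
  rr_res <- if (state$residence == "nursing_home") params$raw$rr_fx_nh
            else params$raw$rr_fx_comm
  trend <- trend_factor(params, state$t)
  p <- params$raw$p_general[k, ] * trend * rr_ost * rr_hist * rr_res
  if (any(p > 1)) {
    warning(sum(p > 1), " annual fracture probabilities clipped to 1")
  }
  pmin(pmax(p, 0), 1)
}

trend_factor <- function(params, t) {
  if (params$raw$trend_g == 0) return(1)
  (1 + params$raw$trend_g)^(t - 1)
}

#' Draw dichotomous events from probabilities and uniforms
#'
#' An event fires when the uniform is smaller than or equal to the event
#' probability; draws are independent across types, so several fracture types
#' can co-occur in the same interval.
#'
#' @param probabilities Numeric vector of probabilities in \[0, 1\].
#' @param u Uniform draws of the same length.
#' @return Logical vector.
#' @export
draw_events <- function(probabilities, u) {
  stopifnot(length(probabilities) == length(u),
            all(probabilities >= 0 & probabilities <= 1))
  u <= probabilities
}

#' Nursing-home entry decision for one interval
#'
#' Entry is possible only for community-dwelling women of at least the
#' minimum entry age (65). A fracture-related entry is considered first,
#' using the highest type-specific admission probability among this
#' interval's hospitalized fractures (entry within three months of the
#' hospital stay); failing that, background (any-cause) entry is drawn.
#' Entry is absorbing.
#'
#' @param state A `woman_state`.
#' @param acute_hospitalized Named logical vector over fracture types:
#'   hospitalized fractures of the current interval.
#' @param params A `parameter_set`.
#' @param u_fracture,u_background Uniform draws for the two decisions.
#' @return One of `"none"`, `"fracture"`, `"background"`.
#' @export
nh_entry_decision <- function(state, acute_hospitalized, params,
                              u_fracture, u_background) {
  if (state$residence == "nursing_home" ||
      state$age < params$raw$nh_min_entry_age) {
    return("none")
  }
  k <- age_class_index(state$age)
  if (any(acute_hospitalized)) {
    p_fx <- max(params$raw$nh_admission[k, acute_hospitalized])
    if (u_fracture <= p_fx) return("fracture")
  }
  if (u_background <= params$bg_entry[k]) return("background")
  "none"
}

#' Counterfactual background nursing-home entry
#'
#' The parallel background track draws any-cause nursing-home entry from its
#' own decision slot, independent of the fracture pathway. It feeds only the
#' long-term-care cost attribution: fracture-attributable LTC stops once the
#' counterfactual track would have institutionalized the woman anyway.
#'
#' @param state A `woman_state`.
#' @param params A `parameter_set`.
#' @param u Uniform draw.
#' @return `TRUE` if the counterfactual track enters this interval.
#' @export
background_nh_counterfactual <- function(state, params, u) {
  if (state$bg_cf_entered || state$age < params$raw$nh_min_entry_age) {
    return(FALSE)
  }
  u <= params$bg_entry[age_class_index(state$age)]
}

# mortality bucket occupancy for a fracture history at interval t:
# years-since-fracture 1 (same interval), 2-5, 6-10; beyond 10 years no excess
mortality_fracture_rr <- function(fx_years, t, k, params) {
  rr <- 1
  for (j in seq_len(6)) {
    ys <- fx_years[[j]]
    if (!length(ys)) next
    ysf <- t - ys + 1L
    for (b in unique(pmin(findInterval(ysf, c(1, 2, 6, 11)), 4L))) {
      if (b <= 3L) rr <- max(rr, params$raw$mort_rr[k, j, b])
    }
  }
  rr
}

#' Annual death probability for a woman's current state
#'
#' All-cause mortality of the generation life table multiplied by the
#' residence multiplier and by the highest fracture excess-mortality
#' multiplier over all fractures in the history (years-since-fracture buckets
#' 1, 2-5, 6-10; no excess beyond ten years; wrist fractures carry none).
#'
#' @param state A `woman_state` (alive); current-interval fractures must
#'   already be part of `fx_years`.
#' @param params A `parameter_set`.
#' @return Annual death probability, clipped to at most 1.
#' @export
mortality_probability <- function(state, params) {
  if (!state$alive) stop("state must be alive")
  k <- age_class_index(state$age)
  q <- params$raw$q_all[as.character(state$age)]
  rr_res <- if (state$residence == "nursing_home") params$raw$rr_mort_nh
            else params$raw$rr_mort_comm
  rr_fx <- mortality_fracture_rr(state$fx_years, state$t, k, params)
  min(unname(q) * rr_res * rr_fx, 1)
}

#' Simulate one yearly interval
#'
#' Within-interval order: osteoporosis onset, fracture draws (with
#' post-onset probabilities), hospitalization and rehabilitation draws, the
#' nursing-home entry decision, the counterfactual background draw, then the
#' survival draw with the current interval's fractures already counted in the
#' mortality multiplier. Fractures become "previous" only from the next
#' interval on.
#'
#' @param state A `woman_state` (alive, age < 100).
#' @param params A `parameter_set`.
#' @param seed Master seed.
#' @return List with the updated `state` and a one-row data frame `record`.
#' @export
step_year <- function(state, params, seed) {
  if (!state$alive || state$age >= 100) stop("state must be alive, age < 100")
  i <- state$person_index
  t <- state$t
  k <- age_class_index(state$age)
  draw <- function(slot) crn_uniform1(seed, i, t, slot)

  onset <- FALSE
  if (state$risk_group == "average_risk" && !state$osteoporotic) {
    onset <- draw(SLOT_OSTEO_ONSET) <= params$q_onset[k]
    if (onset) state$osteoporotic <- TRUE
  }

  p <- annual_fracture_probabilities(state, params)
  fx <- stats::setNames(logical(6), fracture_types())
  hosp <- fx
  rehab <- fx
  for (j in seq_len(6)) {
    if (p[j] > 0) fx[j] <- draw(SLOT_FRACTURE[j]) <= p[j]
    if (fx[j]) {
      hosp[j] <- draw(SLOT_HOSPITAL[j]) <= params$raw$hosp_prob[j]
      if (hosp[j]) rehab[j] <- draw(SLOT_REHAB[j]) <= params$raw$rehab_prob[j]
    }
  }

  nh_entry <- nh_entry_decision(state, hosp, params,
                                draw(SLOT_NH_FRACTURE),
                                draw(SLOT_NH_BACKGROUND))
  if (nh_entry != "none") {
    state$residence <- "nursing_home"
    state$residence_cause <- nh_entry
    state$nh_entry_year <- t
  }

  bg_cf <- background_nh_counterfactual(state, params,
                                        draw(SLOT_NH_COUNTERFACTUAL))
  if (bg_cf) {
    state$bg_cf_entered <- TRUE
    state$bg_cf_year <- t
  }

  for (j in which(fx)) state$fx_years[[j]] <- c(state$fx_years[[j]], t)
  died <- draw(SLOT_SURVIVAL) <= mortality_probability(state, params)

  record <- data.frame(
    t = t, age = state$age,
    model_year = as.integer(params$raw$base_year) + t - 1L,
    osteo_onset = onset, nh_entry = nh_entry, bg_cf_entry = bg_cf,
    died = died, stringsAsFactors = FALSE
  )
  for (j in seq_len(6)) {
    f <- fracture_types()[j]
    record[[paste0("fx_", f)]] <- fx[j]
    record[[paste0("hosp_", f)]] <- hosp[j]
    record[[paste0("rehab_", f)]] <- rehab[j]
  }

  if (died) {
    state$alive <- FALSE
  } else {
    state$age <- state$age + 1L
    state$has_prev <- state$has_prev || any(fx)
  }
  state$t <- t + 1L
  list(state = state, record = record)
}

#' Simulate one woman from preload to death or age 100
#'
#' Runs [preload_state()] and then [step_year()] until death or until the
#' woman completes the interval in which she reaches 100 (intervals have
#' start ages `start_age..99`).
#'
#' @param scenario A [scenario_spec()].
#' @param params A `parameter_set`.
#' @param seed Master seed.
#' @param person_index Person index for the CRN substream.
#' @return A `person_history`: the scenario, final state, and one record per
#'   simulated interval.
#' @export
simulate_individual <- function(scenario, params, seed, person_index = 1L) {
  state <- preload_state(scenario, params, seed, person_index)
  records <- vector("list", 101L - scenario$start_age)
  n <- 0L
  while (state$alive && state$age < 100) {
    out <- step_year(state, params, seed)
    state <- out$state
    n <- n + 1L
    records[[n]] <- out$record
  }
  hist <- list(scenario = scenario, person_index = as.integer(person_index),
               seed = seed, records = do.call(rbind, records[seq_len(n)]),
               final_state = state)
  class(hist) <- "person_history"
  hist
}

#' @export
print.person_history <- function(x, ...) {
  r <- x$records
  cat(sprintf("<person_history> person %d, scenario %s: %d intervals, %s\n",
              x$person_index, x$scenario$label, nrow(r),
              if (any(r$died)) sprintf("died at age %d", max(r$age))
              else "exited alive at 100"))
  invisible(x)
}
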