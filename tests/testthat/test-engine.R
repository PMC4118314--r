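# Per-woman engine: preload, event ordering, nursing-home entry, mortality,
# and exact agreement between the scalar and vectorized paths.

test_that("scenarios enumerate the valid start combinations", {
  specs <- all_scenarios()
  expect_length(specs, 18)
  labels <- vapply(specs, function(s) s$label, "")
  expect_length(unique(labels), 18)
  expect_false(any(grepl("^50_N", labels)))
  expect_error(scenario_spec(50, "N", "avO", "nP"), "65")
})

test_that("preload forces or draws the start characteristics", {
  p <- default_params_cached()
  st <- preload_state(scenario_spec(75, "N", "O", "P"), p, seed = 1)
  expect_true(st$osteoporotic)
  expect_true(st$has_prev)
  expect_identical(st$residence, "nursing_home")
  expect_identical(st$risk_group, "average_risk")

  st <- preload_state(scenario_spec(50, "C", "nO", "nP"), p, seed = 1)
  expect_false(st$osteoporotic)
  expect_false(st$has_prev)
  expect_identical(st$risk_group, "never_osteoporosis")

  # prevalence draws are deterministic given (seed, person)
  a <- preload_state(scenario_spec(50, "C", "avO", "prevalence"), p, 7, 3)
  b <- preload_state(scenario_spec(50, "C", "avO", "prevalence"), p, 7, 3)
  expect_identical(a, b)
  # and follow the shipped prevalence in aggregate
  drawn <- vapply(1:4000, function(i)
    preload_state(scenario_spec(50, "C", "avO", "prevalence"), p, 7,
                  i)$osteoporotic, TRUE)
  expect_lt(abs(mean(drawn) - p$ost_prevalence[1]),
            3 * sqrt(p$ost_prevalence[1] / 4000))
})

test_that("events fire exactly when the uniform does not exceed p", {
  expect_true(draw_events(0.3, 0.3))
  expect_false(draw_events(0.3, 0.3 + 1e-12))
  expect_identical(draw_events(c(0, 1), c(0.5, 0.5)), c(FALSE, TRUE))
})

test_that("fracture probabilities multiply the calibrated risk factors", {
  p <- default_params_cached()
  st <- make_state(age = 72, osteoporotic = TRUE, has_prev = TRUE)
  k <- age_class_index(72)
  got <- annual_fracture_probabilities(st, p)
  want <- p$raw$p_general[k, ] * p$rr_ost[k, ] * p$rr_noprev[k] *
    p$rr_prev_type * p$raw$rr_fx_comm
  expect_equal(got, want)

  st_nh <- make_state(age = 72, residence = "nursing_home")
  got_nh <- annual_fracture_probabilities(st_nh, p)
  expect_equal(got_nh, p$raw$p_general[k, ] * p$rr_noost[k, ] *
                 p$rr_noprev[k] * p$raw$rr_fx_nh)
})

test_that("nursing-home entry uses the largest admission probability", {
  p <- default_params_cached()
  st <- make_state(age = 80)
  k <- age_class_index(80)
  hosp <- stats::setNames(c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
                          fracture_types())
  p_hip <- p$raw$nh_admission[k, "hip"]
  p_wrist <- p$raw$nh_admission[k, "wrist"]
  expect_gt(p_hip, p_wrist)
  # a draw between the smaller and the larger admission probability still
  # admits: the decision uses the maximum over this interval's fractures
  u_mid <- (p_wrist + p_hip) / 2
  expect_identical(nh_entry_decision(st, hosp, p, u_mid, 1), "fracture")
  expect_identical(nh_entry_decision(st, hosp, p, p_hip + 1e-9, 1), "none")
  # background entry when no fracture admits
  expect_identical(
    nh_entry_decision(st, hosp, p, 1, p$bg_entry[k]), "background")
  # no entry below the minimum age or for nursing-home residents
  expect_identical(nh_entry_decision(make_state(age = 60), hosp, p, 0, 0),
                   "none")
  st_nh <- make_state(age = 80, residence = "nursing_home")
  expect_identical(nh_entry_decision(st_nh, hosp, p, 0, 0), "none")
})

test_that("mortality uses the highest open excess-risk bucket", {
  p <- default_params_cached()
  raw <- p$raw
  k <- age_class_index(75)
  rr <- function(fx, t) osteosim:::mortality_fracture_rr(
    modifyList(stats::setNames(rep(list(integer()), 6), fracture_types()),
               fx), t, k, p)
  expect_equal(rr(list(), 10), 1)
  expect_equal(rr(list(hip = 10L), 10), raw$mort_rr[k, "hip", 1])
  expect_equal(rr(list(hip = 8L), 10), raw$mort_rr[k, "hip", 2])
  expect_equal(rr(list(hip = 3L), 10), raw$mort_rr[k, "hip", 3])
  expect_equal(rr(list(hip = 1L), 11), 1)          # more than ten years ago
  expect_equal(rr(list(wrist = 10L), 10), 1)       # wrist: no excess
  # maximum over the whole history, not the most recent fracture
  expect_equal(rr(list(hip = 3L, humerus = 10L), 10),
               max(raw$mort_rr[k, "hip", 3], raw$mort_rr[k, "humerus", 1]))

  st <- make_state(age = 75, t = 26, residence = "nursing_home",
                   fx_years = list(hip = 26L))
  expect_equal(mortality_probability(st, p),
               min(unname(raw$q_all["75"]) * raw$rr_mort_nh *
                     raw$mort_rr[k, "hip", 1], 1))
})

test_that("a woman in a zero-risk world exits alive after 50 intervals", {
  tw <- toy_world("no_mortality_flat_hazard")
  h <- simulate_individual(scenario_spec(50, "C", "nO", "nP"), tw$params,
                           seed = 3)
  expect_equal(nrow(h$records), 50)
  expect_equal(h$records$age, 50:99)
  expect_false(any(h$records$died))
  expect_true(h$final_state$alive)
  expect_equal(h$final_state$age, 100)
})

test_that("certain first-interval death produces a single record", {
  tw <- toy_world("certain_death_year1")
  h <- simulate_individual(scenario_spec(50, "C", "nO", "nP"), tw$params,
                           seed = 3)
  expect_equal(nrow(h$records), 1)
  expect_true(h$records$died)
  expect_false(h$final_state$alive)
})

test_that("repeated simulation of the same woman is identical", {
  p <- default_params_cached()
  scen <- scenario_spec(50, "C", "avO", "prevalence")
  expect_identical(simulate_individual(scen, p, seed = 11, person_index = 8),
                   simulate_individual(scen, p, seed = 11, person_index = 8))
})

test_that("scalar and vectorized paths agree person by person", {
  p <- default_params_cached()
  for (scen in list(scenario_spec(50, "C", "avO", "prevalence"),
                    scenario_spec(75, "N", "O", "P"))) {
    n <- 120
    res <- simulate_cohort(scen, p, n, seed = 19)
    for (i in seq_len(n)) {
      h <- simulate_individual(scen, p, seed = 19, person_index = i)
      counts <- vapply(fracture_types(), function(f)
        sum(h$records[[paste0("fx_", f)]]), 0L)
      expect_equal(unname(res$counts[i, ]), unname(as.numeric(counts)))
      totals <- person_cost_totals(h, p)
      expect_equal(unname(res$cost_undiscounted[i, ]),
                   unname(totals["undiscounted", ]), tolerance = 1e-10)
      expect_equal(unname(res$cost_discounted[i, ]),
                   unname(totals["discounted", ]), tolerance = 1e-10)
      expect_equal(res$death_age[i],
                   if (any(h$records$died)) max(h$records$age)
                   else NA_integer_)
    }
  }
})
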