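# Cost engine: unit-cost attachment, LTC attribution, productivity losses,
# discounting, and ledger conservation.

test_that("discounting matches the closed form", {
  expect_equal(discount(25759, 2019), 25759 / 1.03^10)
  expect_equal(discount(100, 2009), 100)
  expect_equal(discount(100, 2011, rate = 0.05), 100 / 1.05^2)
  expect_error(discount(1, 2008), "base_year")
})

test_that("acute fracture costs follow the care pathway", {
  p <- default_params_cached()
  uc <- p$raw$unit_costs
  hip <- acute_fracture_costs("hip", TRUE, TRUE, 70, "community", p)
  expect_equal(hip[["hospital"]], uc["hip", "hospital"])
  expect_equal(hip[["rehabilitation"]], uc["hip", "rehabilitation"])
  expect_equal(hip[["outpatient"]], 0)
  expect_equal(hip[["home_care"]], uc["hip", "home_care"])
  expect_equal(hip[["informal_care"]], uc["hip", "informal_care"])

  # non-hospitalized: outpatient only; under 66 no home or informal care
  wrist <- acute_fracture_costs("wrist", FALSE, FALSE, 55, "community", p)
  expect_equal(wrist[["outpatient"]], uc["wrist", "outpatient_only"])
  expect_equal(sum(wrist[c("hospital", "rehabilitation", "home_care",
                           "informal_care")]), 0)

  # institutionalized women accrue no home or informal care
  nh <- acute_fracture_costs("hip", TRUE, FALSE, 80, "nursing_home", p)
  expect_equal(nh[["home_care"]], 0)
  expect_equal(nh[["informal_care"]], 0)
  expect_equal(nh[["hospital"]], uc["hip", "hospital"])
})

test_that("LTC attribution walkthrough books 2.5 annual amounts", {
  tw <- toy_world("nh_attribution_walkthrough")
  ltc <- ltc_attribution(tw$history, tw$params)
  expect_equal(ltc$t, 5:7)
  expect_equal(ltc$amount,
               tw$params$raw$ltc_yearly * c(0.5, 1, 1))
  expect_equal(sum(ltc$amount), tw$expected$ltc_attributed)
  expect_equal(sum(ltc$amount), 64397.5)
})

test_that("LTC attribution stops at counterfactual entry and needs a fracture cause", {
  tw <- toy_world("nh_attribution_walkthrough")
  h <- tw$history
  # counterfactual entry in the same year as the fracture entry: nothing
  h$final_state$bg_cf_year <- h$final_state$nh_entry_year
  expect_equal(nrow(ltc_attribution(h, tw$params)), 0)
  # background-caused residence: nothing
  h2 <- tw$history
  h2$final_state$residence_cause <- "background"
  expect_equal(nrow(ltc_attribution(h2, tw$params)), 0)
  # no counterfactual entry: attribution runs to the last interval
  h3 <- tw$history
  h3$final_state$bg_cf_entered <- FALSE
  h3$final_state$bg_cf_year <- NA_integer_
  expect_equal(sum(ltc_attribution(h3, tw$params)$amount),
               tw$params$raw$ltc_yearly * 5.5)
})

test_that("morbidity productivity losses use employment, wage growth and friction", {
  tw <- toy_world("nh_attribution_walkthrough")
  p <- tw$params
  prod <- productivity_costs(tw$history, p)
  # morbidity rows of the hip fracture at t = 5, age 54 (the death at age 59
  # books separate rows at t = 10)
  raw <- p$raw
  daily <- raw$yearly_earnings / raw$work_days_per_year
  emp <- unname(raw$employment[age_class_index(54)])
  grow <- (1 + raw$wage_growth)^4
  hca <- prod$amount[prod$sector == "productivity_hca" & prod$t == 5]
  fca <- prod$amount[prod$sector == "productivity_fca" & prod$t == 5]
  expect_equal(hca, emp * daily * grow * raw$days_lost[["hip"]])
  expect_equal(fca, emp * daily * grow *
                 min(raw$days_lost[["hip"]],
                     raw$friction_years * raw$work_days_per_year))
  expect_lte(fca, hca)
})

test_that("a fracture-attributable death books the lost earnings stream", {
  p <- default_params_cached()
  raw <- p$raw
  # synthetic one-interval history: hip fracture and death at age 50
  scen <- scenario_spec(50, "C", "nO", "nP")
  recs <- data.frame(t = 1L, age = 50L, model_year = 2009L,
                     osteo_onset = FALSE, nh_entry = "none",
                     bg_cf_entry = FALSE, died = TRUE,
                     stringsAsFactors = FALSE)
  for (f in fracture_types()) {
    recs[[paste0("fx_", f)]] <- f == "hip"
    recs[[paste0("hosp_", f)]] <- f == "hip"
    recs[[paste0("rehab_", f)]] <- FALSE
  }
  st <- make_state(age = 50, t = 2)
  st$alive <- FALSE
  st$fx_years$hip <- 1L
  h <- list(scenario = scen, person_index = 1L, seed = 0L, records = recs,
            final_state = st)
  class(h) <- "person_history"

  prod <- productivity_costs(h, p)
  # mortality stream: ages 50..64, first year half-weighted, wages growing
  offs <- 0:(raw$retirement_age - 1 - 50)
  emp50 <- unname(raw$employment[age_class_index(50)])
  want <- unname(raw$employment[age_class_index(50 + offs)]) *
    raw$yearly_earnings *
    (1 + raw$wage_growth)^(1 + offs - 1) * ifelse(offs == 0, 0.5, 1)
  # the morbidity row for the fracture itself is also present
  morb <- emp50 *
    (raw$yearly_earnings / raw$work_days_per_year) * raw$days_lost[["hip"]]
  expect_equal(sum(prod$amount[prod$sector == "productivity_hca"]),
               sum(want) + morb)
  fca_rows <- prod$amount[prod$sector == "productivity_fca"]
  expect_equal(sum(fca_rows),
               emp50 * (raw$yearly_earnings / raw$work_days_per_year) *
                 min(raw$days_lost[["hip"]],
                     raw$friction_years * raw$work_days_per_year) +
                 emp50 * raw$yearly_earnings * raw$friction_years)

  # a wrist-only history carries no excess mortality, hence no death loss
  recs2 <- recs
  for (f in fracture_types()) {
    recs2[[paste0("fx_", f)]] <- f == "wrist"
    recs2[[paste0("hosp_", f)]] <- FALSE
  }
  st2 <- st
  st2$fx_years$hip <- integer()
  st2$fx_years$wrist <- 1L
  h2 <- h
  h2$records <- recs2
  h2$final_state <- st2
  prod2 <- productivity_costs(h2, p)
  expect_false(any(prod2$model_year > 2009))
})

test_that("the ledger conserves totals and discounting never inflates", {
  p <- default_params_cached()
  scen <- scenario_spec(50, "C", "avO", "prevalence")
  for (i in 1:25) {
    h <- simulate_individual(scen, p, seed = 4, person_index = i)
    led <- person_ledger(h, p)
    tot <- person_cost_totals(h, p)
    expect_equal(sum(tot["undiscounted", ]), sum(led$amount))
    expect_equal(sum(tot["discounted", ]), sum(led$discounted))
    expect_true(all(led$discounted <= led$amount + 1e-12))
    expect_true(all(led$amount >= 0))
    if (nrow(led)) {
      expect_true(all(led$t >= 1 & led$t <= max(h$records$t)))
    }
  }
})

test_that("zero unit costs and earnings give an all-zero ledger", {
  raw <- default_params_cached()$raw
  raw$unit_costs[!is.na(raw$unit_costs)] <- 0
  raw$ltc_yearly <- 0
  raw$yearly_earnings <- 0
  p0 <- finalize_parameter_set(raw)
  h <- simulate_individual(scenario_spec(50, "C", "avO", "prevalence"), p0,
                           seed = 21, person_index = 2)
  expect_equal(sum(person_cost_totals(h, p0)), 0)
})
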