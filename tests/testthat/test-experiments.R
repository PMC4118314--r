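# Experiment layer: paired base case, scenarios, deterministic sensitivity,
# probabilistic sensitivity analysis.

test_that("identical-risk paired cohorts have exactly zero excess", {
  raw <- default_params_cached()$raw
  raw$gradient[] <- 1
  p1 <- finalize_parameter_set(raw)
  s <- run_base_case(p1, n = 1500, seed = 5)
  expect_identical(unname(s$counts$excess), rep(0, 6))
  expect_identical(unname(s$direct[["excess_discounted"]]), 0)
  expect_true(all(s$sectors$excess_undiscounted == 0))
})

test_that("scenario runs cover all 18 combinations with coherent costs", {
  p <- default_params_cached()
  out <- run_scenarios(p, n = 400, seed = 9)
  expect_equal(nrow(out), 18)
  expect_equal(anyDuplicated(out$label), 0)
  expect_false(any(out$start_age == 50 & out$residence == "N"))
  expect_true(all(out$direct_discounted <= out$direct_undiscounted))
  expect_true(all(out$direct_undiscounted >= 0))
})

test_that("nursing-home scenarios accrue no community-only costs", {
  p <- default_params_cached()
  res <- simulate_cohort(scenario_spec(75, "N", "avO", "prevalence"), p,
                         400, seed = 9)
  expect_equal(sum(res$cost_undiscounted[, "home_care"]), 0)
  expect_equal(sum(res$cost_undiscounted[, "informal_care"]), 0)
  expect_equal(sum(res$cost_undiscounted[, "long_term_care"]), 0)
})

test_that("the twenty sensitivity specifications transform the inputs", {
  specs <- sensitivity_specs()
  expect_length(specs, 20)
  expect_identical(names(specs), paste0("S", 1:20))
  p <- default_params_cached()
  expect_equal(apply_sensitivity(p, "S20")$raw$discount_rate, 0.05)
  expect_true(all(apply_sensitivity(p, "S3")$raw$mort_rr == 1))
  expect_true(all(apply_sensitivity(p, "S6")$rr_noprev == 1))
  expect_equal(apply_sensitivity(p, "S13")$raw$p_general,
               pmin(p$raw$p_general * 1.3, 1))
  expect_equal(apply_sensitivity(p, "S19")$raw$trend_g, -0.02)
  s15 <- apply_sensitivity(p, "S15")
  expect_true(all(s15$raw$nh_admission[, -1] == 0))
  expect_equal(s15$raw$nh_admission[, "hip"], p$raw$nh_admission[, "hip"])
  # the identity transformation leaves the parameters unchanged
  expect_equal(apply_sensitivity(p, NULL), p)
  expect_error(apply_sensitivity(p, "S21"), "unknown")
})

test_that("probability scaling moves excess costs in opposite directions", {
  p <- default_params_cached()
  out <- run_sensitivity(p, ids = c("S13", "S14", "S20"), n = 3000,
                         seed = 31)
  base <- attr(out, "base_excess_discounted")
  expect_gt(base, 0)
  expect_gt(out$pct_change[out$id == "S13"], 0)
  expect_lt(out$pct_change[out$id == "S14"], 0)
  # a higher discount rate strictly reduces the discounted excess
  expect_lt(out$excess_discounted[out$id == "S20"], base)
})

test_that("collapsed uncertainty reproduces the point estimate", {
  p <- default_params_cached()
  raw <- p$raw
  raw$grad_lo <- raw$gradient
  raw$grad_hi <- raw$gradient
  raw$prevfx$rr_any_ci <- rep(raw$prevfx$rr_any, 2)
  raw$prevfx$rr_hip_ci <- rep(raw$prevfx$rr_hip, 2)
  raw$prevfx$rr_osteo_ci <- rep(raw$prevfx$rr_osteo, 2)
  p0 <- finalize_parameter_set(raw)
  drawn <- draw_psa_parameters(p0, seed = 13, cv = 0)
  expect_equal(drawn$raw$p_general, p0$raw$p_general)
  expect_equal(drawn$raw$unit_costs, p0$raw$unit_costs)
  expect_equal(drawn$raw$gradient, p0$raw$gradient)
  expect_equal(drawn$raw$mort_rr, p0$raw$mort_rr)
  expect_equal(drawn$rr_noprev, p0$rr_noprev)
})

test_that("sampled parameters keep their means and invariants", {
  p <- default_params_cached()
  # moment check of the beta sampler
  m <- 0.3
  cv <- 0.2
  draws <- osteosim:::local_seed(99, osteosim:::rbeta_mean(20000, m, cv))
  expect_lt(abs(mean(draws) - m), 3 * (cv * m) / sqrt(20000))
  expect_true(all(draws > 0 & draws < 1))
  g <- osteosim:::local_seed(99, osteosim:::rgamma_mean(20000, 500, 0.2))
  expect_lt(abs(mean(g) - 500), 3 * 100 / sqrt(20000))
  # drawn sets still satisfy the calibration identity
  d <- draw_psa_parameters(p, seed = 77, cv = 0.2)
  for (k in 1:10) {
    prev <- d$ost_prevalence[k]
    expect_equal(unname(prev * d$rr_ost[k, ] + (1 - prev) * d$rr_noost[k, ]),
                 rep(1, 6), tolerance = 1e-12)
  }
  expect_false(identical(d$raw$p_general, p$raw$p_general))
})

test_that("a small probabilistic analysis brackets its own median", {
  p <- default_params_cached()
  psa <- run_psa(p, m = 6, n = 300, seed = 3, cv = 0.1)
  expect_equal(nrow(psa$draws), 6)
  iv <- psa$intervals
  expect_true(all(iv$p2.5 <= iv$median + 1e-12))
  expect_true(all(iv$median <= iv$p97.5 + 1e-12))
  # reproducible
  psa2 <- run_psa(p, m = 6, n = 300, seed = 3, cv = 0.1)
  expect_equal(psa$draws, psa2$draws)
})
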