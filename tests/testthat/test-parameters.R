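# Shipped parameter tables and parameter-set construction.

test_that("shipped probability and cost tables match the printed values", {
  gp <- table1_probabilities()
  expect_equal(dim(gp), c(10, 6))
  expect_equal(gp["50-54", "hip"], 0.00038)
  expect_equal(gp["80-84", "hip"], 0.01605)
  expect_equal(gp["95+", "hip"], 0.03960)
  expect_true(all(gp > 0 & gp < 1))
  # hip risk rises monotonically with age
  expect_true(all(diff(gp[, "hip"]) > 0))

  uc <- table2_unit_costs()
  expect_equal(unname(uc[, "hospital"]),
               c(8554, 8395, 6324, 5764, 5005, 3794))
  expect_equal(uc["hip", "rehabilitation"], 2187)
  expect_true(is.na(uc["hip", "outpatient_only"]))
  expect_true(is.na(uc["other_femur", "outpatient_only"]))
  expect_equal(uc["wrist", "informal_care"], 581)
  expect_equal(uc["wrist", "home_care"], 525)
})

test_that("default parameter set carries the headline settings", {
  p <- default_params_cached()
  expect_equal(p$raw$ltc_yearly, 25759)
  expect_equal(p$raw$discount_rate, 0.03)
  expect_equal(p$raw$base_year, 2009)
  expect_equal(p$raw$wage_growth, 0.02)
  expect_equal(unname(p$raw$hosp_prob[c("hip", "other_femur")]), c(1, 1))
  expect_equal(p$raw$nh_min_entry_age, 65)
})

test_that("emitted tables round-trip through the reader and validate", {
  dir <- tempfile("params")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  write_default_tables(dir)
  tabs <- read_parameter_tables(dir)
  p <- build_parameter_set(tabs)
  expect_s3_class(p, "parameter_set")
  # identical to the copy shipped inside the installed package
  shipped <- read_parameter_tables(system.file("extdata", "parameters",
                                               package = "osteosim"))
  expect_equal(tabs, shipped)
})

test_that("validation collects all input errors before failing", {
  tabs <- default_tables()
  tabs$general_fracture_probabilities$value[1] <- -0.2
  tabs$fracture_mortality_rr$value[
    tabs$fracture_mortality_rr$fracture_type == "wrist"][1] <- 2
  err <- tryCatch(build_parameter_set(tabs), error = conditionMessage)
  expect_match(err, "general")
  expect_match(err, "wrist")
})

test_that("derived calibrations make the subgroup mixes average to one", {
  p <- default_params_cached()
  for (k in 1:10) {
    prev <- p$ost_prevalence[k]
    expect_equal(unname(prev * p$rr_ost[k, ] + (1 - prev) * p$rr_noost[k, ]),
                 rep(1, 6), tolerance = 1e-12)
    pf <- p$raw$prevfx$prevalence[k]
    expect_equal(unname(pf * p$raw$prevfx$rr_any * p$rr_noprev[k] +
                          (1 - pf) * p$rr_noprev[k]), 1, tolerance = 1e-12)
  }
  # onset probabilities reproduce the prevalence ladder over each span
  for (k in 1:9) {
    expect_equal(unname(1 - (1 - p$ost_prevalence[k]) *
                          (1 - p$q_onset[k])^5),
                 unname(max(p$ost_prevalence[k + 1], p$ost_prevalence[k])),
                 tolerance = 1e-12)
  }
})

test_that("random valid parameter sets satisfy every invariant", {
  for (s in c(2, 17, 404)) {
    p <- random_valid_parameters(s)
    raw <- p$raw
    expect_true(all(raw$p_general >= 0 & raw$p_general <= 1))
    expect_true(all(raw$hosp_prob > 0 & raw$hosp_prob <= 1))
    expect_equal(unname(raw$hosp_prob[c("hip", "other_femur")]), c(1, 1))
    expect_true(all(raw$gradient >= 1))
    expect_true(all(raw$mort_rr[, "wrist", ] == 1))
    expect_true(all(raw$mort_rr >= 1))
    for (k in 1:10) {
      prev <- p$ost_prevalence[k]
      expect_equal(unname(prev * p$rr_ost[k, ] +
                            (1 - prev) * p$rr_noost[k, ]),
                   rep(1, 6), tolerance = 1e-12)
    }
  }
  expect_false(identical(random_valid_parameters(1)$raw$p_general,
                         random_valid_parameters(2)$raw$p_general))
})

test_that("placeholder provenance is tracked per table", {
  p <- default_params_cached()
  man <- placeholder_manifest(p)
  expect_true(all(c("table", "rows", "placeholders") %in% names(man)))
  expect_gt(sum(man$placeholders), 0)
  # the printed tables themselves contain no placeholders
  expect_equal(man$placeholders[man$table ==
                                  "general_fracture_probabilities"], 0)
})
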