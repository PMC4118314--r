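# Experiment layer: base case with CRN-paired excess estimation, the 18
# start-characteristic scenarios, the 20 deterministic sensitivity analyses,
# probabilistic sensitivity analysis, and internal validation.

#' Base-case paired simulation of the two risk groups
#'
#' Simulates the average-osteoporosis-risk cohort and the
#' never-osteoporosis cohort with identical CRN substreams and reports
#' lifetime fracture counts and costs per capita together with the excess
#' (average risk minus never osteoporosis), the cost attributable to
#' osteoporosis.
#'
#' @param params A `parameter_set`.
#' @param n Women per risk group (the study scale is 200,000).
#' @param seed Master seed.
#' @param start_age Start age (default 50).
#' @return A `cohort_summary`.
#' @export
run_base_case <- function(params, n = 200000, seed = 1L, start_age = 50) {
  avg <- simulate_cohort(scenario_spec(start_age, "C", "avO", "prevalence"),
                         params, n, seed)
  nev <- simulate_cohort(scenario_spec(start_age, "C", "nO", "prevalence"),
                         params, n, seed)
  summarize_pair(avg, nev)
}

#' Summarize a CRN-paired pair of cohorts
#'
#' @param average,never `cohort_result`s of the average-risk and
#'   never-osteoporosis groups run with the same seed and n.
#' @return A `cohort_summary` with per-type counts, per-sector and per-type
#'   costs (discounted and undiscounted), excess, attribution percentages,
#'   and the annual per-capita cost-by-age series of both groups.
#' @export
summarize_pair <- function(average, never) {
  stopifnot(average$n == never$n, average$seed == never$seed)
  a <- aggregate_cohort(average)
  b <- aggregate_cohort(never)
  pct <- function(x, ref) ifelse(ref > 0, 100 * x / ref, NA_real_)

  counts <- data.frame(
    fracture_type = fracture_types(),
    average_risk = unname(a$mean_counts),
    never_osteoporosis = unname(b$mean_counts),
    excess = unname(a$mean_counts - b$mean_counts),
    attribution_pct = unname(pct(a$mean_counts - b$mean_counts,
                                 a$mean_counts)),
    stringsAsFactors = FALSE
  )
  sectors <- data.frame(
    sector = COST_SECTORS,
    average_undiscounted = unname(a$sector_undiscounted),
    never_undiscounted = unname(b$sector_undiscounted),
    excess_undiscounted = unname(a$sector_undiscounted -
                                   b$sector_undiscounted),
    average_discounted = unname(a$sector_discounted),
    never_discounted = unname(b$sector_discounted),
    excess_discounted = unname(a$sector_discounted - b$sector_discounted),
    stringsAsFactors = FALSE
  )
  types <- data.frame(
    fracture_type = fracture_types(),
    average_undiscounted = unname(a$type_undiscounted),
    never_undiscounted = unname(b$type_undiscounted),
    excess_undiscounted = unname(a$type_undiscounted - b$type_undiscounted),
    average_discounted = unname(a$type_discounted),
    never_discounted = unname(b$type_discounted),
    excess_discounted = unname(a$type_discounted - b$type_discounted),
    stringsAsFactors = FALSE
  )
  out <- list(
    n = average$n, seed = average$seed,
    counts = counts, sectors = sectors, types = types,
    direct = c(average_undiscounted = a$direct_undiscounted,
               never_undiscounted = b$direct_undiscounted,
               excess_undiscounted = a$direct_undiscounted -
                 b$direct_undiscounted,
               average_discounted = a$direct_discounted,
               never_discounted = b$direct_discounted,
               excess_discounted = a$direct_discounted - b$direct_discounted),
    cost_by_age = list(average = a$cost_per_capita_by_age,
                       never = b$cost_per_capita_by_age),
    average = average, never = never
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d per risk group, seed = %d\n",
              x$n, x$seed))
  cat("\nLifetime fracture counts per woman:\n")
  print(transform(x$counts,
                  average_risk = round(average_risk, 3),
                  never_osteoporosis = round(never_osteoporosis, 3),
                  excess = round(excess, 3),
                  attribution_pct = round(attribution_pct, 1)),
        row.names = FALSE)
  cat("\nDiscounted direct lifetime costs per woman (EUR):\n")
  cat(sprintf("  average risk %8.0f\n  never osteo  %8.0f\n  excess       %8.0f (%.1f%% of average)\n",
              x$direct["average_discounted"], x$direct["never_discounted"],
              x$direct["excess_discounted"],
              100 * x$direct["excess_discounted"] /
                x$direct["average_discounted"]))
  invisible(x)
}

#' Run the 18 start-characteristic scenarios
#'
#' Simulates each valid combination of start age, residence, disease status
#' and fracture history separately and reports per-capita direct lifetime
#' costs, undiscounted and discounted.
#'
#' @param params A `parameter_set`.
#' @param n Women per scenario.
#' @param seed Master seed.
#' @return Data frame with one row per scenario.
#' @export
run_scenarios <- function(params, n = 20000, seed = 1L) {
  specs <- all_scenarios()
  rows <- lapply(specs, function(s) {
    agg <- aggregate_cohort(simulate_cohort(s, params, n, seed))
    data.frame(label = s$label, start_age = s$start_age,
               residence = s$residence, disease = s$disease,
               history = s$history,
               direct_undiscounted = agg$direct_undiscounted,
               direct_discounted = agg$direct_discounted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The 20 deterministic sensitivity specifications
#'
#' @return Named list mapping `S1`..`S20` to a short description.
#' @export
sensitivity_specs <- function() {
  list(
    S1 = "informal care valued at the opportunity-cost wage rate",
    S2 = "informal care valued at the minimum wage rate",
    S3 = "no fracture excess mortality",
    S4 = "fracture excess mortality only in the first year",
    S5 = "30% of first-year fracture excess mortality, none thereafter",
    S6 = "previous fracture not a risk factor",
    S7 = "previous-fracture RRs at the lower 95% confidence limit",
    S8 = "previous-fracture RRs at the upper 95% confidence limit",
    S9 = "BMD gradients of risk at the lower value",
    S10 = "BMD gradients of risk at the upper value",
    S11 = "osteoporosis prevalence +30%",
    S12 = "osteoporosis prevalence -30%",
    S13 = "all fracture probabilities +30%",
    S14 = "all fracture probabilities -30%",
    S15 = "only hip fractures trigger nursing-home admission",
    S16 = "fracture incidence trend +1% per year",
    S17 = "fracture incidence trend -1% per year",
    S18 = "fracture incidence trend +2% per year",
    S19 = "fracture incidence trend -2% per year",
    S20 = "discount rate 5%"
  )
}

#' Apply one deterministic sensitivity transformation
#'
#' Each specification modifies only its declared raw inputs and recomputes
#' the derived calibrations; applying no specification recovers the base
#' case.
#'
#' @param params A `parameter_set`.
#' @param id One of `"S1"`..`"S20"`, or `NULL` for the unchanged base case.
#' @return A transformed `parameter_set`.
#' @export
apply_sensitivity <- function(params, id = NULL) {
  raw <- params$raw
  if (is.null(id)) return(finalize_parameter_set(raw))
  switch(id,
    S1 = raw$informal_factor <- raw$informal_opportunity_factor,
    S2 = raw$informal_factor <- raw$informal_minimum_factor,
    S3 = raw$mort_rr[, , ] <- 1,
    S4 = raw$mort_rr[, , 2:3] <- 1,
    S5 = {
      raw$mort_rr[, , 1] <- 1 + 0.3 * (raw$mort_rr[, , 1] - 1)
      raw$mort_rr[, , 2:3] <- 1
    },
    S6 = raw$use_prevfx <- FALSE,
    S7 = {
      raw$prevfx$rr_any <- raw$prevfx$rr_any_ci[1]
      raw$prevfx$rr_hip <- raw$prevfx$rr_hip_ci[1]
      raw$prevfx$rr_osteo <- raw$prevfx$rr_osteo_ci[1]
    },
    S8 = {
      raw$prevfx$rr_any <- raw$prevfx$rr_any_ci[2]
      raw$prevfx$rr_hip <- raw$prevfx$rr_hip_ci[2]
      raw$prevfx$rr_osteo <- raw$prevfx$rr_osteo_ci[2]
    },
    S9 = raw$gradient <- raw$grad_lo,
    S10 = raw$gradient <- raw$grad_hi,
    S11 = raw$ost_prev_scale <- 1.3,
    S12 = raw$ost_prev_scale <- 0.7,
    S13 = raw$p_general <- pmin(raw$p_general * 1.3, 1),
    S14 = raw$p_general <- raw$p_general * 0.7,
    S15 = raw$nh_admission[, fracture_types() != "hip"] <- 0,
    S16 = raw$trend_g <- 0.01,
    S17 = raw$trend_g <- -0.01,
    S18 = raw$trend_g <- 0.02,
    S19 = raw$trend_g <- -0.02,
    S20 = raw$discount_rate <- 0.05,
    stop("unknown sensitivity id: ", id)
  )
  finalize_parameter_set(raw)
}

#' Deterministic one-way sensitivity analysis
#'
#' Re-runs the paired base case under each transformed parameter set (same
#' seed, so the comparison is CRN-paired and free of first-order noise) and
#' reports the percentage change of the discounted direct excess cost
#' relative to the base case.
#'
#' @param params A `parameter_set`.
#' @param ids Character vector of spec identifiers (default all 20).
#' @param n Women per risk group and run.
#' @param seed Master seed.
#' @param start_age Start age.
#' @return Data frame with columns `id`, `description`, `excess_discounted`,
#'   `pct_change`.
#' @export
run_sensitivity <- function(params, ids = names(sensitivity_specs()),
                            n = 20000, seed = 1L, start_age = 50) {
  specs <- sensitivity_specs()
  stopifnot(all(ids %in% names(specs)))
  base <- run_base_case(params, n, seed, start_age)
  base_excess <- base$direct[["excess_discounted"]]
  rows <- lapply(ids, function(id) {
    s <- run_base_case(apply_sensitivity(params, id), n, seed, start_age)
    ex <- s$direct[["excess_discounted"]]
    data.frame(id = id, description = specs[[id]], excess_discounted = ex,
               pct_change = 100 * (ex - base_excess) / base_excess,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "base_excess_discounted") <- base_excess
  out
}

#' Internal validation against the input incidence table
#'
#' Simulates the average-risk population and compares the modeled annual
#' fracture incidence per age class and type (fractures divided by
#' person-years lived in the class) with the expected general-population
#' input probabilities. Also reports the distribution of lifetime fracture
#' counts per woman (0 to 6+) for each type.
#'
#' @param params A `parameter_set`.
#' @param n Number of women.
#' @param seed Master seed.
#' @param start_age Start age.
#' @return List with `rates` (data frame: age_class, fracture_type,
#'   expected, modeled), `count_distribution` (matrix: 0..6+ by type), and
#'   the underlying `cohort_result`.
#' @export
internal_validation <- function(params, n = 200000, seed = 1L,
                                start_age = 50) {
  res <- simulate_cohort(scenario_spec(start_age, "C", "avO", "prevalence"),
                         params, n, seed)
  modeled <- sweep(res$fx_by_class, 1, pmax(res$py_by_class, 1), "/")
  modeled[res$py_by_class == 0, ] <- NA_real_
  rates <- data.frame(
    age_class = rep(age_classes(), times = 6),
    fracture_type = rep(fracture_types(), each = 10),
    expected = as.vector(params$raw$p_general),
    modeled = as.vector(modeled),
    person_years = rep(unname(res$py_by_class), times = 6),
    stringsAsFactors = FALSE
  )
  dist <- vapply(fracture_types(), function(f) {
    ct <- pmin(res$counts[, f], 6L)
    tabulate(ct + 1L, nbins = 7L) / res$n
  }, numeric(7))
  rownames(dist) <- c(0:5, "6+")
  list(rates = rates, count_distribution = dist, result = res)
}

# ---------------------------------------------------------------------------
# probabilistic sensitivity analysis

local_seed <- function(s, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(s)
  code
}

rbeta_mean <- function(n, mean, cv) {
  # moment-matched beta; degenerate at cv = 0 or at the {0, 1} boundary
  mean <- rep(mean, length.out = n)
  out <- mean
  ok <- mean > 0 & mean < 1 & cv > 0
  if (any(ok)) {
    sd <- pmin(cv * mean, 0.95 * sqrt(mean * (1 - mean)))
    nu <- mean * (1 - mean) / sd^2 - 1
    out[ok] <- stats::rbeta(sum(ok), (mean * nu)[ok], ((1 - mean) * nu)[ok])
  }
  out
}

rgamma_mean <- function(n, mean, cv) {
  mean <- rep(mean, length.out = n)
  out <- mean
  ok <- mean > 0 & cv > 0
  if (any(ok)) {
    out[ok] <- stats::rgamma(sum(ok), shape = 1 / cv^2,
                             scale = (mean * cv^2)[ok])
  }
  out
}

rlnorm_rr <- function(n, point, lo = NULL, hi = NULL, cv = 0.2) {
  # relative risks: lognormal with median at the point estimate; spread from
  # the 95% CI when available, else from the coefficient of variation
  point <- rep(point, length.out = n)
  if (all(point == 1)) return(point)
  sdlog <- if (!is.null(lo) && !is.null(hi) && all(hi > lo)) {
    (log(hi) - log(lo)) / (2 * 1.96)
  } else {
    sqrt(log(1 + cv^2))
  }
  if (all(sdlog == 0)) return(point)
  stats::rlnorm(n, meanlog = log(point), sdlog = sdlog)
}

#' Draw one probabilistic parameter set
#'
#' Samples the second-order parameter uncertainty: probabilities and
#' prevalences from moment-matched beta distributions, unit costs from gamma
#' distributions, relative risks from lognormal distributions (spread from
#' published confidence intervals where shipped, else from `cv`). Derived
#' calibrations are recomputed, so every drawn set satisfies the consistency
#' identities.
#'
#' @param params A `parameter_set`.
#' @param seed Seed for the parameter draw.
#' @param cv Default coefficient of variation where no interval is shipped.
#' @return A perturbed `parameter_set`.
#' @export
draw_psa_parameters <- function(params, seed, cv = 0.2) {
  raw <- params$raw
  local_seed(seed, {
    raw$p_general[] <- pmin(rbeta_mean(60, as.vector(raw$p_general), cv), 1)
    raw$rehab_prob[] <- rbeta_mean(6, raw$rehab_prob, cv)
    keep1 <- raw$hosp_prob == 1
    raw$hosp_prob[] <- ifelse(keep1, 1, rbeta_mean(6, raw$hosp_prob, cv))
    raw$nh_admission[] <- rbeta_mean(60, as.vector(raw$nh_admission), cv)
    raw$care_prev[] <- sort(rbeta_mean(10, raw$care_prev, cv))
    raw$prevfx$prevalence[] <- sort(rbeta_mean(10, raw$prevfx$prevalence, cv))

    uc <- as.vector(raw$unit_costs)
    uc[!is.na(uc)] <- rgamma_mean(sum(!is.na(uc)), uc[!is.na(uc)], cv)
    raw$unit_costs[] <- uc
    raw$ltc_yearly <- rgamma_mean(1, raw$ltc_yearly, cv)

    raw$prevfx$rr_any <- rlnorm_rr(1, raw$prevfx$rr_any,
                                   raw$prevfx$rr_any_ci[1],
                                   raw$prevfx$rr_any_ci[2], cv = cv)
    raw$prevfx$rr_hip <- rlnorm_rr(1, raw$prevfx$rr_hip,
                                   raw$prevfx$rr_hip_ci[1],
                                   raw$prevfx$rr_hip_ci[2], cv = cv)
    raw$prevfx$rr_osteo <- rlnorm_rr(1, raw$prevfx$rr_osteo,
                                     raw$prevfx$rr_osteo_ci[1],
                                     raw$prevfx$rr_osteo_ci[2], cv = cv)
    raw$gradient[] <- pmax(rlnorm_rr(60, as.vector(raw$gradient),
                                     as.vector(raw$grad_lo),
                                     as.vector(raw$grad_hi), cv = cv), 1)
    raw$mort_rr[] <- pmax(rlnorm_rr(180, as.vector(raw$mort_rr), cv = cv), 1)
    raw$mort_rr[, "wrist", ] <- 1
    raw$rr_mort_nh <- rlnorm_rr(1, raw$rr_mort_nh, cv = cv)
    raw$rr_mort_comm <- rlnorm_rr(1, raw$rr_mort_comm, cv = cv)
  })
  finalize_parameter_set(raw)
}

#' Probabilistic sensitivity analysis
#'
#' Runs `m` outer parameter draws; each draw is a CRN-paired base case of
#' `n` women per risk group. Uncertainty intervals use the percentile method
#' (2.5 and 97.5).
#'
#' @param params A `parameter_set`.
#' @param m Number of outer simulations (the study used 1,500).
#' @param n Women per risk group per simulation (the study used 10,000).
#' @param seed Master seed.
#' @param cv Default coefficient of variation for parameters without a
#'   shipped interval; `cv = 0` collapses every distribution to its point
#'   value.
#' @param start_age Start age.
#' @return List with `draws` (one row per simulation: excess counts and
#'   costs) and `intervals` (2.5%, 50%, 97.5% percentiles per quantity).
#' @export
run_psa <- function(params, m = 1500, n = 10000, seed = 1L, cv = 0.2,
                    start_age = 50) {
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    sub <- (as.numeric(seed) * 7919 + i * 104729) %% 2147483647
    p_i <- draw_psa_parameters(params, sub, cv)
    s <- run_base_case(p_i, n, sub, start_age)
    rows[[i]] <- c(
      stats::setNames(s$counts$average_risk,
                      paste0("count_avg_", s$counts$fracture_type)),
      stats::setNames(s$counts$excess,
                      paste0("count_excess_", s$counts$fracture_type)),
      direct_avg_discounted = s$direct[["average_discounted"]],
      direct_never_discounted = s$direct[["never_discounted"]],
      direct_excess_discounted = s$direct[["excess_discounted"]],
      direct_excess_undiscounted = s$direct[["excess_undiscounted"]]
    )
  }
  draws <- do.call(rbind, rows)
  intervals <- t(apply(draws, 2, stats::quantile,
                       probs = c(0.025, 0.5, 0.975), names = FALSE))
  colnames(intervals) <- c("p2.5", "median", "p97.5")
  list(draws = as.data.frame(draws), intervals = as.data.frame(intervals),
       m = m, n = n, seed = seed, cv = cv)
}
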