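# Vectorized cohort engine.
#
# Simulates n women of one scenario simultaneously, year by year, applying
# exactly the same decision rules, decision-slot order and CRN draw scheme as
# the per-woman reference path (preload_state / step_year / person_ledger).
# All women of a cohort share the start age, so age, age class, discount
# factor and trend factor are scalars within an interval and every decision
# is a length-n vector operation.

#' Simulate a cohort of women through the fracture model
#'
#' Runs `n` women of one scenario with per-person CRN substreams, booking
#' costs as events occur. Deterministic for fixed `(scenario, params, n,
#' seed)`; two cohorts run with the same seed are paired person by person
#' (common random numbers), which [run_base_case()] exploits for excess
#' estimation.
#'
#' @param scenario A [scenario_spec()].
#' @param params A `parameter_set`.
#' @param n Number of women (>= 1).
#' @param seed Master seed (nonnegative integer below 2^31).
#' @return A `cohort_result` with per-person fracture counts and cost totals,
#'   death ages, incidence tallies by age class, and the annual cost-by-age
#'   series.
#' @export
simulate_cohort <- function(scenario, params, n, seed) {
  stopifnot(inherits(scenario, "scenario_spec"), n >= 1)
  raw <- params$raw
  ft <- fracture_types()
  start_age <- scenario$start_age
  n <- as.integer(n)

  # --- preload ------------------------------------------------------------
  k0 <- age_class_index(start_age)
  ost <- switch(scenario$disease,
    O = rep(TRUE, n),
    nO = rep(FALSE, n),
    avO = crn_uniform(seed, n, 0L, SLOT_PRELOAD_OSTEO) <=
      params$ost_prevalence[k0])
  has_prev <- switch(scenario$history,
    P = rep(TRUE, n),
    nP = rep(FALSE, n),
    prevalence = crn_uniform(seed, n, 0L, SLOT_PRELOAD_PREVFX) <=
      raw$prevfx$prevalence[k0])
  average_group <- scenario$disease != "nO"

  alive <- rep(TRUE, n)
  res_nh <- rep(scenario$residence == "N", n)
  cause_fx <- rep(FALSE, n)
  nh_entry_t <- rep(NA_integer_, n)
  bg_cf <- rep(FALSE, n)
  bg_cf_t <- rep(NA_integer_, n)
  death_age <- rep(NA_integer_, n)

  counts <- matrix(0L, n, 6, dimnames = list(NULL, ft))
  cost_u <- matrix(0, n, length(COST_SECTORS),
                   dimnames = list(NULL, COST_SECTORS))
  cost_d <- cost_u
  by_type_u <- stats::setNames(numeric(6), ft)
  by_type_d <- by_type_u
  fx_by_class <- matrix(0, 10, 6, dimnames = list(age_classes(), ft))
  py_by_class <- stats::setNames(numeric(10), age_classes())
  ages_all <- start_age:99
  cost_by_age <- stats::setNames(numeric(length(ages_all)), ages_all)
  alive_by_age <- cost_by_age
  clipped <- 0L

  # 10-year ring buffer of fracture years per type (mortality windows)
  fxh <- lapply(1:6, function(j) matrix(FALSE, n, 10))

  out_cost <- ifelse(is.na(raw$unit_costs[, "outpatient_only"]), 0,
                     raw$unit_costs[, "outpatient_only"])
  daily <- raw$yearly_earnings / raw$work_days_per_year
  friction_days <- raw$friction_years * raw$work_days_per_year
  n_years <- 100L - start_age

  for (t in seq_len(n_years)) {
    if (!any(alive)) break
    a <- start_age + t - 1L
    k <- age_class_index(a)
    disc_f <- 1 / (1 + raw$discount_rate)^(t - 1)
    trend <- trend_factor(params, t)
    wage_g <- (1 + raw$wage_growth)^(t - 1)

    py_by_class[k] <- py_by_class[k] + sum(alive)
    alive_by_age[as.character(a)] <- sum(alive)

    # 1. osteoporosis onset
    if (average_group && params$q_onset[k] > 0) {
      u <- crn_uniform(seed, n, t, SLOT_OSTEO_ONSET)
      ost <- ost | (alive & !ost & u <= params$q_onset[k])
    }

    # 2./3. fracture, hospitalization, rehabilitation draws
    rr_hist_base <- params$rr_noprev[k]
    year_direct <- numeric(n)
    col_t <- (t - 1L) %% 10L + 1L
    any_fx <- rep(FALSE, n)
    hosp_list <- vector("list", 6)
    for (j in 1:6) {
      p <- raw$p_general[k, j] * trend *
        ifelse(ost, params$rr_ost[k, j], params$rr_noost[k, j]) *
        rr_hist_base * ifelse(has_prev, params$rr_prev_type[j], 1) *
        ifelse(res_nh, raw$rr_fx_nh[j], raw$rr_fx_comm[j])
      over <- p > 1
      if (any(over)) {
        clipped <- clipped + sum(over & alive)
        p <- pmin(p, 1)
      }
      fx <- alive & crn_uniform(seed, n, t, SLOT_FRACTURE[j]) <= p
      hosp <- fx & crn_uniform(seed, n, t, SLOT_HOSPITAL[j]) <= raw$hosp_prob[j]
      rehab <- hosp &
        crn_uniform(seed, n, t, SLOT_REHAB[j]) <= raw$rehab_prob[j]
      hosp_list[[j]] <- hosp
      any_fx <- any_fx | fx
      fxh[[j]][, col_t] <- fx

      nfx <- sum(fx)
      if (nfx) {
        counts[, j] <- counts[, j] + fx
        fx_by_class[k, j] <- fx_by_class[k, j] + nfx
        # acute direct costs
        amt_hosp <- ifelse(hosp, raw$unit_costs[j, "hospital"], 0)
        amt_rehab <- ifelse(rehab, raw$unit_costs[j, "rehabilitation"], 0)
        amt_out <- ifelse(fx & !hosp, out_cost[j], 0)
        care <- fx & !res_nh & a > 65
        amt_home <- ifelse(care, raw$unit_costs[j, "home_care"], 0)
        amt_inf <- ifelse(care, raw$unit_costs[j, "informal_care"] *
                            raw$informal_factor, 0)
        cost_u[, "hospital"] <- cost_u[, "hospital"] + amt_hosp
        cost_u[, "rehabilitation"] <- cost_u[, "rehabilitation"] + amt_rehab
        cost_u[, "outpatient"] <- cost_u[, "outpatient"] + amt_out
        cost_u[, "home_care"] <- cost_u[, "home_care"] + amt_home
        cost_u[, "informal_care"] <- cost_u[, "informal_care"] + amt_inf
        direct_j <- amt_hosp + amt_rehab + amt_out + amt_home + amt_inf
        cost_d[, "hospital"] <- cost_d[, "hospital"] + amt_hosp * disc_f
        cost_d[, "rehabilitation"] <- cost_d[, "rehabilitation"] +
          amt_rehab * disc_f
        cost_d[, "outpatient"] <- cost_d[, "outpatient"] + amt_out * disc_f
        cost_d[, "home_care"] <- cost_d[, "home_care"] + amt_home * disc_f
        cost_d[, "informal_care"] <- cost_d[, "informal_care"] +
          amt_inf * disc_f
        tot_j <- sum(direct_j)
        by_type_u[j] <- by_type_u[j] + tot_j
        by_type_d[j] <- by_type_d[j] + tot_j * disc_f
        year_direct <- year_direct + direct_j
        # productivity (morbidity)
        if (a < raw$retirement_age) {
          emp <- raw$employment[k]
          hca <- ifelse(fx, emp * daily * wage_g * raw$days_lost[j], 0)
          fca <- ifelse(fx, emp * daily * wage_g *
                          min(raw$days_lost[j], friction_days), 0)
          cost_u[, "productivity_hca"] <- cost_u[, "productivity_hca"] + hca
          cost_u[, "productivity_fca"] <- cost_u[, "productivity_fca"] + fca
          cost_d[, "productivity_hca"] <- cost_d[, "productivity_hca"] +
            hca * disc_f
          cost_d[, "productivity_fca"] <- cost_d[, "productivity_fca"] +
            fca * disc_f
        }
      }
    }

    # 4. nursing-home entry (fracture entry first, then background)
    eligible <- alive & !res_nh & a >= raw$nh_min_entry_age
    if (any(eligible)) {
      p_adm <- numeric(n)
      for (j in 1:6) {
        if (raw$nh_admission[k, j] > 0) {
          p_adm <- pmax(p_adm, ifelse(hosp_list[[j]],
                                      raw$nh_admission[k, j], 0))
        }
      }
      fx_entry <- eligible & p_adm > 0 &
        crn_uniform(seed, n, t, SLOT_NH_FRACTURE) <= p_adm
      bg_entry <- eligible & !fx_entry &
        crn_uniform(seed, n, t, SLOT_NH_BACKGROUND) <= params$bg_entry[k]
      res_nh <- res_nh | fx_entry | bg_entry
      cause_fx <- cause_fx | fx_entry
      nh_entry_t[fx_entry] <- t
    }

    # 5. counterfactual background track
    if (a >= raw$nh_min_entry_age) {
      cand <- alive & !bg_cf
      new_cf <- cand &
        crn_uniform(seed, n, t, SLOT_NH_COUNTERFACTUAL) <= params$bg_entry[k]
      bg_cf <- bg_cf | new_cf
      bg_cf_t[new_cf] <- t
    }

    # fracture-attributable long-term care (half-cycle on the entry year)
    book <- alive & cause_fx & !bg_cf
    if (any(book)) {
      amt <- ifelse(book,
                    raw$ltc_yearly * ifelse(!is.na(nh_entry_t) &
                                              nh_entry_t == t, 0.5, 1), 0)
      cost_u[, "long_term_care"] <- cost_u[, "long_term_care"] + amt
      cost_d[, "long_term_care"] <- cost_d[, "long_term_care"] + amt * disc_f
      year_direct <- year_direct + amt
    }

    # 6. survival
    rr_fx <- rep(1, n)
    for (j in 1:6) {
      if (all(params$raw$mort_rr[k, j, ] == 1)) next
      m <- fxh[[j]]
      occ1 <- m[, col_t]
      # years-since-fracture 2..5 -> fracture years t-4..t-1; 6..10 -> t-9..t-5
      cols2 <- (t - 4):(t - 1); cols2 <- cols2[cols2 >= 1]
      cols3 <- (t - 9):(t - 5); cols3 <- cols3[cols3 >= 1]
      if (length(cols2)) {
        occ2 <- rowSums(m[, (cols2 - 1L) %% 10L + 1L, drop = FALSE]) > 0
        rr_fx <- pmax(rr_fx, ifelse(occ2, raw$mort_rr[k, j, 2], 1))
      }
      if (length(cols3)) {
        occ3 <- rowSums(m[, (cols3 - 1L) %% 10L + 1L, drop = FALSE]) > 0
        rr_fx <- pmax(rr_fx, ifelse(occ3, raw$mort_rr[k, j, 3], 1))
      }
      rr_fx <- pmax(rr_fx, ifelse(occ1, raw$mort_rr[k, j, 1], 1))
    }
    q <- pmin(raw$q_all[as.character(a)] *
                ifelse(res_nh, raw$rr_mort_nh, raw$rr_mort_comm) * rr_fx, 1)
    died <- alive & crn_uniform(seed, n, t, SLOT_SURVIVAL) <= q

    # productivity (mortality) for fracture-attributable deaths
    dd <- died & rr_fx > 1
    if (a < raw$retirement_age && any(dd)) {
      offs <- 0:(raw$retirement_age - 1L - a)
      emp_s <- raw$employment[age_class_index(a + offs)]
      gr <- (1 + raw$wage_growth)^(t - 1 + offs)
      hc <- ifelse(offs == 0, 0.5, 1)
      hca_u <- sum(emp_s * raw$yearly_earnings * gr * hc)
      hca_d <- sum(emp_s * raw$yearly_earnings * gr * hc /
                     (1 + raw$discount_rate)^(t - 1 + offs))
      fca_u <- raw$employment[k] * raw$yearly_earnings * wage_g *
        raw$friction_years
      cost_u[dd, "productivity_hca"] <- cost_u[dd, "productivity_hca"] + hca_u
      cost_d[dd, "productivity_hca"] <- cost_d[dd, "productivity_hca"] + hca_d
      cost_u[dd, "productivity_fca"] <- cost_u[dd, "productivity_fca"] + fca_u
      cost_d[dd, "productivity_fca"] <- cost_d[dd, "productivity_fca"] +
        fca_u * disc_f
    }

    cost_by_age[as.character(a)] <- sum(year_direct)
    death_age[died] <- a
    alive <- alive & !died
    has_prev <- has_prev | any_fx
  }

  res <- list(
    scenario = scenario, n = n, seed = seed,
    counts = counts, cost_undiscounted = cost_u, cost_discounted = cost_d,
    by_type_undiscounted = by_type_u, by_type_discounted = by_type_d,
    death_age = death_age, fx_by_class = fx_by_class,
    py_by_class = py_by_class, cost_by_age = cost_by_age,
    alive_by_age = alive_by_age, clipped = clipped
  )
  class(res) <- "cohort_result"
  res
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %s, n = %d, seed = %d\n",
              x$scenario$label, x$n, x$seed))
  cat("  mean lifetime fracture counts:\n")
  print(round(colMeans(x$counts), 4))
  cat("  mean discounted direct cost:",
      round(mean(rowSums(x$cost_discounted[, DIRECT_SECTORS, drop = FALSE]))),
      "EUR\n")
  invisible(x)
}

#' Per-capita aggregation of a cohort run
#'
#' @param result A `cohort_result`.
#' @return List with mean lifetime fracture counts per type, mean costs per
#'   sector (discounted and undiscounted), mean direct costs by fracture type
#'   (excluding long-term care, which attaches to the nursing-home episode,
#'   not to a fracture type), and the annual per-capita direct cost-by-age
#'   series.
#' @export
aggregate_cohort <- function(result) {
  stopifnot(inherits(result, "cohort_result"))
  per_age <- ifelse(result$alive_by_age > 0,
                    result$cost_by_age / result$alive_by_age, NA_real_)
  list(
    n = result$n,
    mean_counts = colMeans(result$counts),
    sector_undiscounted = colMeans(result$cost_undiscounted),
    sector_discounted = colMeans(result$cost_discounted),
    type_undiscounted = result$by_type_undiscounted / result$n,
    type_discounted = result$by_type_discounted / result$n,
    direct_undiscounted = mean(rowSums(
      result$cost_undiscounted[, DIRECT_SECTORS, drop = FALSE])),
    direct_discounted = mean(rowSums(
      result$cost_discounted[, DIRECT_SECTORS, drop = FALSE])),
    cost_per_capita_by_age = per_age
  )
}
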