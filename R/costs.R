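# Cost engine: unit-cost attachment, the parallel-track long-term-care
# attribution, productivity losses (human-capital and friction-cost
# approaches), and discounting to the base year.
#
# All sector names used in ledgers and summaries:
COST_SECTORS <- c("hospital", "rehabilitation", "long_term_care",
                  "outpatient", "home_care", "informal_care",
                  "productivity_hca", "productivity_fca")
DIRECT_SECTORS <- COST_SECTORS[1:6]

#' Discount an amount to the base year
#'
#' @param amount Amount in base-year prices.
#' @param model_year Calendar year the amount accrues in (>= `base_year`).
#' @param rate Annual discount rate (default 3%).
#' @param base_year Base year (default 2009).
#' @return Present value `amount / (1 + rate)^(model_year - base_year)`.
#' @export
#' @examples
#' discount(25759, 2019) # about 19167.1
discount <- function(amount, model_year, rate = 0.03, base_year = 2009) {
  if (any(model_year < base_year)) stop("model_year must be >= base_year")
  amount / (1 + rate)^(model_year - base_year)
}

#' Direct costs of one acute fracture
#'
#' Hospitalized fractures incur the hospital unit cost (which bundles
#' post-hospital outpatient aftercare) plus, if drawn, inpatient
#' rehabilitation; non-hospitalized fractures incur the outpatient-only cost.
#' Professional home care and informal care are added only for
#' community-dwelling women older than 65. Residence is taken at the start of
#' the interval (the fracture happened before any nursing-home entry of the
#' same interval).
#'
#' @param type Fracture type.
#' @param hospitalized,rehab Logical event flags for this fracture.
#' @param age Age at the interval start.
#' @param residence `"community"` or `"nursing_home"`.
#' @param params A `parameter_set`.
#' @return Named numeric vector over the direct cost sectors.
#' @export
acute_fracture_costs <- function(type, hospitalized, rehab, age, residence,
                                 params) {
  uc <- params$raw$unit_costs[type, ]
  out <- stats::setNames(numeric(length(DIRECT_SECTORS)), DIRECT_SECTORS)
  if (hospitalized) {
    out["hospital"] <- uc[["hospital"]]
    if (rehab) out["rehabilitation"] <- uc[["rehabilitation"]]
  } else {
    out["outpatient"] <- uc[["outpatient_only"]]
  }
  if (age > 65 && residence == "community") {
    out["home_care"] <- uc[["home_care"]]
    out["informal_care"] <- uc[["informal_care"]] * params$raw$informal_factor
  }
  out
}

#' Fracture-attributable long-term-care amounts of one history
#'
#' Yearly nursing-home costs are attributed to the fracture pathway only
#' while the woman is institutionalized because of a fracture AND the
#' counterfactual background track has not yet institutionalized her for any
#' other reason. The entry year is weighted one half (half-cycle correction);
#' attribution stops permanently once the counterfactual track enters, and is
#' zero if the counterfactual entry is not later than the fracture entry.
#'
#' @param history A `person_history`.
#' @param params A `parameter_set`.
#' @return Data frame with columns `t`, `model_year`, `amount` (possibly
#'   zero rows).
#' @export
ltc_attribution <- function(history, params) {
  st <- history$final_state
  empty <- data.frame(t = integer(), model_year = integer(),
                      amount = numeric())
  if (is.na(st$nh_entry_year) || st$residence_cause != "fracture") {
    return(empty)
  }
  entry <- st$nh_entry_year
  last_t <- max(history$records$t)
  stop_t <- if (st$bg_cf_entered) min(st$bg_cf_year - 1L, last_t) else last_t
  if (stop_t < entry) return(empty)
  t <- entry:stop_t
  data.frame(
    t = t,
    model_year = as.integer(params$raw$base_year) + t - 1L,
    amount = params$raw$ltc_yearly * ifelse(t == entry, 0.5, 1)
  )
}

#' Productivity losses of one history
#'
#' Morbidity losses: for each fracture before retirement age, the
#' age-class employment rate times the daily earnings (gross plus employer
#' share, growing with the assumed net wage increase) times the work days
#' lost; the friction-cost approach caps the days at the friction period.
#' Mortality losses apply to a fracture-attributable death (death while a
#' non-wrist fracture's excess-mortality window is open) before retirement
#' age: the human-capital approach books the earnings stream to retirement
#' (half-cycle weight on the first year), the friction-cost approach one
#' friction period of earnings.
#'
#' @param history A `person_history`.
#' @param params A `parameter_set`.
#' @return Data frame with columns `t` (interval of the originating event),
#'   `model_year` (year the amount accrues in), `sector`
#'   (`productivity_hca` / `productivity_fca`), `amount`.
#' @export
productivity_costs <- function(history, params) {
  raw <- params$raw
  recs <- history$records
  rows <- list()
  base <- as.integer(raw$base_year)
  growth <- function(t) (1 + raw$wage_growth)^(t - 1)
  daily <- raw$yearly_earnings / raw$work_days_per_year
  friction_days <- raw$friction_years * raw$work_days_per_year

  for (i in seq_len(nrow(recs))) {
    age <- recs$age[i]
    if (age >= raw$retirement_age) next
    t <- recs$t[i]
    k <- age_class_index(age)
    emp <- raw$employment[k]
    for (f in fracture_types()) {
      if (!recs[[paste0("fx_", f)]][i]) next
      days <- raw$days_lost[f]
      hca <- emp * daily * growth(t) * days
      fca <- emp * daily * growth(t) * min(days, friction_days)
      rows[[length(rows) + 1L]] <- data.frame(
        t = t, model_year = base + t - 1L,
        sector = c("productivity_hca", "productivity_fca"),
        amount = c(hca, fca), stringsAsFactors = FALSE)
    }
  }

  died_i <- which(recs$died)
  if (length(died_i) == 1L) {
    age <- recs$age[died_i]
    t <- recs$t[died_i]
    st <- history$final_state
    rr_fx <- mortality_fracture_rr(st$fx_years, t, age_class_index(age),
                                   params)
    if (age < raw$retirement_age && rr_fx > 1) {
      lost_ages <- age:(raw$retirement_age - 1L)
      offs <- lost_ages - age
      emp <- raw$employment[age_class_index(lost_ages)]
      hca_amt <- emp * raw$yearly_earnings * growth(t + offs) *
        ifelse(offs == 0, 0.5, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        t = t, model_year = base + t - 1L + offs,
        sector = "productivity_hca", amount = hca_amt,
        stringsAsFactors = FALSE)
      fca_amt <- raw$employment[age_class_index(age)] * raw$yearly_earnings *
        growth(t) * raw$friction_years
      rows[[length(rows) + 1L]] <- data.frame(
        t = t, model_year = base + t - 1L,
        sector = "productivity_fca", amount = fca_amt,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(t = integer(), model_year = integer(),
                      sector = character(), amount = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Full cost ledger of one simulated woman
#'
#' Combines acute fracture costs, the long-term-care attribution, and
#' productivity losses into a tidy per-entry ledger with undiscounted and
#' discounted amounts. Every euro traces to one fracture event
#' (`fracture_type` set) or one nursing-home episode / death
#' (`fracture_type` `NA`).
#'
#' @param history A `person_history`.
#' @param params A `parameter_set`.
#' @return Data frame with columns `t`, `model_year`, `sector`,
#'   `fracture_type`, `amount`, `discounted`.
#' @export
person_ledger <- function(history, params) {
  raw <- params$raw
  recs <- history$records
  rows <- list()
  residence <- if (history$scenario$residence == "N") "nursing_home"
               else "community"
  for (i in seq_len(nrow(recs))) {
    for (f in fracture_types()) {
      if (!recs[[paste0("fx_", f)]][i]) next
      am <- acute_fracture_costs(f, recs[[paste0("hosp_", f)]][i],
                                 recs[[paste0("rehab_", f)]][i],
                                 recs$age[i], residence, params)
      am <- am[am > 0]
      if (length(am)) {
        rows[[length(rows) + 1L]] <- data.frame(
          t = recs$t[i], model_year = recs$model_year[i],
          sector = names(am), fracture_type = f, amount = unname(am),
          stringsAsFactors = FALSE)
      }
    }
    if (recs$nh_entry[i] != "none") residence <- "nursing_home"
  }
  ltc <- ltc_attribution(history, params)
  if (nrow(ltc)) {
    rows[[length(rows) + 1L]] <- data.frame(
      t = ltc$t, model_year = ltc$model_year, sector = "long_term_care",
      fracture_type = NA_character_, amount = ltc$amount,
      stringsAsFactors = FALSE)
  }
  prod <- productivity_costs(history, params)
  if (nrow(prod)) {
    rows[[length(rows) + 1L]] <- data.frame(
      t = prod$t, model_year = prod$model_year, sector = prod$sector,
      fracture_type = NA_character_, amount = prod$amount,
      stringsAsFactors = FALSE)
  }
  led <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t = integer(), model_year = integer(), sector = character(),
               fracture_type = character(), amount = numeric(),
               stringsAsFactors = FALSE)
  led$discounted <- discount(led$amount, led$model_year,
                             raw$discount_rate, raw$base_year)
  rownames(led) <- NULL
  led
}

#' Per-sector cost totals of one history
#'
#' @param history A `person_history`.
#' @param params A `parameter_set`.
#' @return Matrix with rows `undiscounted`/`discounted` and one column per
#'   cost sector.
#' @export
person_cost_totals <- function(history, params) {
  led <- person_ledger(history, params)
  out <- matrix(0, 2, length(COST_SECTORS),
                dimnames = list(c("undiscounted", "discounted"),
                                COST_SECTORS))
  if (nrow(led)) {
    out["undiscounted", ] <- vapply(COST_SECTORS, function(s)
      sum(led$amount[led$sector == s]), 1)
    out["discounted", ] <- vapply(COST_SECTORS, function(s)
      sum(led$discounted[led$sector == s]), 1)
  }
  out
}
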