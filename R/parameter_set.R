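#' Build a validated parameter set from input tables
#'
#' Validates all input tables (collecting every failure into a single error),
#' then precomputes the derived, simulation-ready quantities: the
#' osteoporotic / non-osteoporotic relative risks per age class and fracture
#' type (gradient-of-risk calibration plus consistency split), the
#' no-previous-fracture calibration factor, annual osteoporosis-onset
#' probabilities and background nursing-home entry probabilities
#' (prevalence-to-incidence conversion).
#'
#' @param tables Named list of data frames as returned by
#'   [read_parameter_tables()] or [default_tables()].
#' @return An object of class `parameter_set`.
#' @export
build_parameter_set <- function(tables) {
  raw <- parse_parameter_tables(tables)
  finalize_parameter_set(raw)
}

#' Default parameter set shipped with the package
#'
#' Reads the CSV tables installed under `extdata/parameters` and builds the
#' validated [build_parameter_set()] from them.
#'
#' @return A `parameter_set`.
#' @export
default_parameters <- function() {
  dir <- system.file("extdata", "parameters", package = "osteosim")
  if (dir == "") stop("installed default parameter tables not found")
  build_parameter_set(read_parameter_tables(dir))
}

# turn the raw data frames into typed vectors/matrices, collecting all
# validation failures before erroring
parse_parameter_tables <- function(tables) {
  ft <- fracture_types()
  ac <- age_classes()
  errs <- character()
  note <- function(...) errs <<- c(errs, sprintf(...))

  pick_schedule <- function(df, what, lower = -Inf, upper = Inf,
                            fill = NULL) {
    v <- stats::setNames(rep(NA_real_, 10), ac)
    idx <- match(df$age_class, ac)
    if (any(is.na(idx))) {
      note("%s: unknown age class '%s'", what, df$age_class[is.na(idx)][1])
      return(v)
    }
    v[idx] <- df$value
    if (!is.null(fill)) v[is.na(v)] <- fill
    if (any(is.na(v))) note("%s: missing age classes", what)
    bad <- !is.na(v) & (v < lower | v > upper)
    if (any(bad)) note("%s: %d values outside [%g, %g]", what, sum(bad),
                       lower, upper)
    v
  }

  g <- tables$general_fracture_probabilities
  p_general <- matrix(NA_real_, 10, 6, dimnames = list(ac, ft))
  p_general[cbind(match(g$age_class, ac), match(g$fracture_type, ft))] <- g$value
  if (any(is.na(p_general))) note("general_fracture_probabilities: incomplete")
  if (any(p_general < 0 | p_general > 1, na.rm = TRUE)) {
    note("general_fracture_probabilities: values outside [0, 1]")
  }

  h <- tables$hospitalization_rehab
  hosp_prob <- stats::setNames(
    h$value[h$parameter == "hospitalization_prob"][
      match(ft, h$fracture_type[h$parameter == "hospitalization_prob"])], ft)
  rehab_prob <- stats::setNames(
    h$value[h$parameter == "rehab_prob"][
      match(ft, h$fracture_type[h$parameter == "rehab_prob"])], ft)
  if (any(is.na(hosp_prob)) || any(hosp_prob <= 0 | hosp_prob > 1)) {
    note("hospitalization_prob: values must lie in (0, 1]")
  }
  if (!isTRUE(all.equal(unname(hosp_prob[c("hip", "other_femur")]), c(1, 1)))) {
    note("hospitalization_prob: hip and other_femur must be 1.0")
  }
  if (any(is.na(rehab_prob)) || any(rehab_prob < 0 | rehab_prob > 1)) {
    note("rehab_prob: values must lie in [0, 1]")
  }

  pr <- tables$previous_fracture_rr
  grab <- function(p, col = "value") pr[[col]][match(p, pr$parameter)]
  prevfx <- list(
    rr_any   = grab("rr_any_prev"),
    rr_hip   = grab("rr_hip_prev"),
    rr_osteo = grab("rr_osteo_prev"),
    rr_any_ci   = c(grab("rr_any_prev", "low"), grab("rr_any_prev", "high")),
    rr_hip_ci   = c(grab("rr_hip_prev", "low"), grab("rr_hip_prev", "high")),
    rr_osteo_ci = c(grab("rr_osteo_prev", "low"), grab("rr_osteo_prev", "high")),
    prevalence = pick_schedule(tables$previous_fracture_prevalence,
                               "previous_fracture_prevalence", 0, 1)
  )
  if (any(is.na(c(prevfx$rr_any, prevfx$rr_hip, prevfx$rr_osteo))) ||
      any(c(prevfx$rr_any, prevfx$rr_hip, prevfx$rr_osteo) <= 0, na.rm = TRUE)) {
    note("previous_fracture_rr: risk ratios must be > 0")
  }

  bg <- tables$bmd_gradient
  gradient <- matrix(NA_real_, 10, 6, dimnames = list(ac, ft))
  grad_lo <- gradient; grad_hi <- gradient
  for (i in seq_len(nrow(bg))) {
    rows <- if (bg$age_class[i] == "all") 1:10 else match(bg$age_class[i], ac)
    cl <- match(bg$fracture_type[i], ft)
    gradient[rows, cl] <- bg$value[i]
    grad_lo[rows, cl] <- bg$low[i]
    grad_hi[rows, cl] <- bg$high[i]
  }
  if (any(is.na(gradient))) note("bmd_gradient: incomplete")
  if (any(gradient < 1 | grad_lo < 1, na.rm = TRUE)) {
    note("bmd_gradient: gradients must be >= 1")
  }

  tscore <- pick_schedule(tables$mean_tscore, "mean_tscore", -4, 2)

  lt <- tables$life_table
  q_all <- stats::setNames(rep(NA_real_, 51), 50:100)
  q_all[match(lt$age, 50:100)] <- lt$value
  if (any(is.na(q_all)) || any(q_all < 0 | q_all > 1, na.rm = TRUE)) {
    note("life_table: need q in [0, 1] for every age 50..100")
  }

  mr <- tables$fracture_mortality_rr
  buckets <- c("1", "2-5", "6-10")
  mort_rr <- array(NA_real_, c(10, 6, 3), dimnames = list(ac, ft, buckets))
  for (i in seq_len(nrow(mr))) {
    mort_rr[, match(mr$fracture_type[i], ft), match(mr$bucket[i], buckets)] <-
      mr$value[i]
  }
  if (any(is.na(mort_rr)) || any(mort_rr <= 0, na.rm = TRUE)) {
    note("fracture_mortality_rr: need a positive RR per type and bucket")
  }
  if (any(mort_rr[, "wrist", ] != 1, na.rm = TRUE)) {
    note("fracture_mortality_rr: wrist fractures carry no excess mortality")
  }

  rs <- tables$residence
  res_val <- function(p, f = "all") {
    rs$value[rs$parameter == p & rs$fracture_type == f]
  }
  rr_fx_nh <- vapply(ft, function(f) res_val("rr_fracture_nh", f), 1)
  rr_fx_comm <- vapply(ft, function(f) res_val("rr_fracture_community", f), 1)
  rr_mort_nh <- res_val("rr_mortality_nh")
  rr_mort_comm <- res_val("rr_mortality_community")
  nh_share <- res_val("nh_population_share")
  if (any(c(rr_fx_nh, rr_fx_comm, rr_mort_nh, rr_mort_comm) <= 0)) {
    note("residence: relative risks must be > 0")
  }

  nh_admission <- matrix(0, 10, 6, dimnames = list(ac, ft))
  na_tab <- tables$nh_admission
  nh_admission[cbind(match(na_tab$age_class, ac),
                     match(na_tab$fracture_type, ft))] <- na_tab$value
  if (any(nh_admission < 0 | nh_admission > 1)) {
    note("nh_admission: probabilities must lie in [0, 1]")
  }

  care_prev <- pick_schedule(tables$care_prevalence, "care_prevalence",
                             0, 1, fill = 0)

  uc_tab <- tables$unit_costs
  cats <- c("hospital", "rehabilitation", "outpatient_only",
            "home_care", "informal_care")
  unit_costs <- matrix(NA_real_, 6, 5, dimnames = list(ft, cats))
  unit_costs[cbind(match(uc_tab$fracture_type, ft),
                   match(uc_tab$cost_category, cats))] <- uc_tab$value
  # femoral fractures are always hospitalized; no outpatient-only pathway
  if (any(unit_costs < 0, na.rm = TRUE)) note("unit_costs: costs must be >= 0")

  employment <- pick_schedule(tables$employment, "employment", 0, 1)
  dl <- tables$work_days_lost
  days_lost <- stats::setNames(dl$value[match(ft, dl$fracture_type)], ft)
  if (any(is.na(days_lost)) || any(days_lost < 0)) {
    note("work_days_lost: need nonnegative days per fracture type")
  }

  st <- tables$settings
  setting <- function(p) {
    v <- st$value[st$parameter == p]
    if (length(v) != 1) note("settings: missing '%s'", p)
    if (length(v) == 0) NA_real_ else v
  }

  prov <- do.call(rbind, lapply(names(tables), function(nm) {
    df <- tables[[nm]]
    data.frame(table = nm, rows = nrow(df),
               placeholders = sum(df$provenance == "placeholder"),
               stringsAsFactors = FALSE)
  }))

  raw <- list(
    p_general = p_general, hosp_prob = hosp_prob, rehab_prob = rehab_prob,
    prevfx = prevfx, gradient = gradient, grad_lo = grad_lo,
    grad_hi = grad_hi, tscore = tscore,
    bmd_threshold = setting("bmd_threshold"), ost_prev_scale = 1,
    q_all = q_all, mort_rr = mort_rr,
    rr_mort_nh = rr_mort_nh, rr_mort_comm = rr_mort_comm,
    nh_share = nh_share, rr_fx_nh = rr_fx_nh, rr_fx_comm = rr_fx_comm,
    nh_admission = nh_admission, care_prev = care_prev,
    unit_costs = unit_costs,
    ltc_yearly = setting("ltc_yearly_cost"),
    discount_rate = setting("discount_rate"),
    base_year = setting("base_year"),
    wage_growth = setting("wage_growth"),
    retirement_age = setting("retirement_age"),
    nh_min_entry_age = setting("nh_min_entry_age"),
    friction_years = setting("friction_period_years"),
    work_days_per_year = setting("work_days_per_year"),
    yearly_earnings = setting("yearly_earnings"),
    employment = employment, days_lost = days_lost,
    informal_factor = 1,
    informal_opportunity_factor = setting("informal_opportunity_factor"),
    informal_minimum_factor = setting("informal_minimum_factor"),
    trend_g = 0, use_prevfx = TRUE, provenance = prov
  )
  if (length(errs)) {
    stop("parameter validation failed:\n  - ",
         paste(errs, collapse = "\n  - "))
  }
  raw
}

#' Recompute all derived calibration quantities for a parameter set
#'
#' Called by [build_parameter_set()] and again after any sensitivity or
#' probabilistic perturbation of the raw inputs, so the calibration identities
#' (prevalence-weighted subgroup relative risks equal to one) always hold by
#' construction for the current inputs.
#'
#' @param raw Parsed raw inputs (internal structure).
#' @return A `parameter_set`.
#' @export
finalize_parameter_set <- function(raw) {
  ac <- age_classes()
  # osteoporosis prevalence from the unit-SD T-score model, optionally scaled
  ost_prev <- stats::pnorm(raw$bmd_threshold - raw$tscore) * raw$ost_prev_scale
  ost_prev <- pmin(ost_prev, 0.95)

  rr_ost <- raw$gradient
  for (j in seq_len(ncol(rr_ost))) {
    rr_ost[, j] <- rr_osteoporotic(raw$gradient[, j], raw$tscore,
                                   raw$bmd_threshold)
  }
  # note: rr_ost is computed from the *unscaled* T-score distribution; the
  # consistency split below uses the (possibly scaled) prevalence
  if (any(rr_ost * ost_prev >= 1)) {
    stop("inconsistent osteoporosis inputs: rr_ost * prevalence >= 1")
  }
  rr_noost <- rr_ost
  for (j in seq_len(ncol(rr_ost))) {
    rr_noost[, j] <- rr_non_osteoporotic(rr_ost[, j], ost_prev)
  }

  if (raw$use_prevfx) {
    rr_noprev <- rr_no_previous_fracture(raw$prevfx$rr_any,
                                         raw$prevfx$prevalence)
    rr_prev_type <- c(hip = raw$prevfx$rr_hip,
                      stats::setNames(rep(raw$prevfx$rr_osteo, 5),
                                      fracture_types()[-1]))
  } else {
    rr_noprev <- stats::setNames(rep(1, 10), ac)
    rr_prev_type <- stats::setNames(rep(1, 6), fracture_types())
  }

  # annual osteoporosis-onset probability: prevalence ladder between the
  # first ages of consecutive bands; held at zero in the open last band
  q_onset <- stats::setNames(rep(0, 10), ac)
  for (k in 1:9) {
    q_onset[k] <- prevalence_to_incidence(ost_prev[k], ost_prev[k + 1], 5,
                                          floor_negative = TRUE)
  }

  # background NH entry from care prevalence (only from the minimum entry age)
  bg_entry <- stats::setNames(rep(0, 10), ac)
  for (k in 4:9) {
    bg_entry[k] <- prevalence_to_incidence(raw$care_prev[k],
                                           raw$care_prev[k + 1], 5,
                                           floor_negative = TRUE)
  }
  bg_entry[10] <- bg_entry[9]

  # population-consistency of the residence fracture risks (warning only)
  mix <- raw$nh_share * raw$rr_fx_nh + (1 - raw$nh_share) * raw$rr_fx_comm
  if (any(abs(mix - 1) > 0.02)) {
    warning("residence fracture RRs are not population-consistent for: ",
            paste(fracture_types()[abs(mix - 1) > 0.02], collapse = ", "))
  }

  ps <- list(raw = raw, ost_prevalence = ost_prev, rr_ost = rr_ost,
             rr_noost = rr_noost, rr_noprev = rr_noprev,
             rr_prev_type = rr_prev_type, q_onset = q_onset,
             bg_entry = bg_entry)
  class(ps) <- "parameter_set"
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  fracture types: %s\n",
              paste(fracture_types(), collapse = ", ")))
  cat(sprintf("  discount rate %.1f%%, base year %d, LTC %s EUR/year\n",
              100 * x$raw$discount_rate, as.integer(x$raw$base_year),
              format(x$raw$ltc_yearly, big.mark = ",")))
  cat(sprintf("  osteoporosis prevalence %.1f%% (50-54) to %.1f%% (95+)\n",
              100 * x$ost_prevalence[1], 100 * x$ost_prevalence[10]))
  n_ph <- sum(x$raw$provenance$placeholders)
  cat(sprintf("  %d input rows are placeholders for supplement-only values\n",
              n_ph))
  invisible(x)
}

#' List placeholder inputs in a parameter set
#'
#' Returns the per-table manifest of how many shipped rows are placeholder
#' stand-ins for values published only in the study's supplement, so users can
#' see exactly which inputs to replace.
#'
#' @param params A `parameter_set`.
#' @return Data frame with columns `table`, `rows`, `placeholders`.
#' @export
placeholder_manifest <- function(params) {
  stopifnot(inherits(params, "parameter_set"))
  params$raw$provenance
}
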