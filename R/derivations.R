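#' Inflate hospital-based fracture rates to total fracture probabilities
#'
#' Fracture probabilities estimated from hospital discharge counts miss cases
#' treated exclusively in the outpatient sector. Dividing the hospital-based
#' annual case rate by the (age-independent) hospitalization probability of the
#' fracture type recovers the total annual fracture probability.
#'
#' @param hospital_case_rate Annual hospitalized-case probability per
#'   person-year (>= 0).
#' @param hospitalization_prob Probability that a fracture of this type is
#'   treated in hospital, in (0, 1].
#' @return Total annual fracture probability, clipped to at most 1 (a warning
#'   is raised if clipping occurred).
#' @export
#' @examples
#' derive_total_fracture_probability(0.003, 0.6) # 0.005
derive_total_fracture_probability <- function(hospital_case_rate,
                                              hospitalization_prob) {
  if (any(hospitalization_prob <= 0) || any(hospitalization_prob > 1)) {
    stop("hospitalization_prob must lie in (0, 1]")
  }
  if (any(hospital_case_rate < 0)) stop("hospital_case_rate must be >= 0")
  p <- hospital_case_rate / hospitalization_prob
  if (any(p > 1)) {
    warning(sum(p > 1), " total fracture probabilities clipped to 1")
    p <- pmin(p, 1)
  }
  p
}

#' Relative fracture risk of women without a previous fracture
#'
#' Published previous-fracture risk ratios compare women with a prior fracture
#' to women without one, while the simulation's reference rates describe the
#' whole female general population. Splitting the population by
#' previous-fracture prevalence gives the relative risk of the no-previous-
#' fracture subgroup versus the general population:
#' `RR = 1 / (1 + (rr_any_prev - 1) * prev)`.
#'
#' The prevalence-weighted average of the two subgroup risks is then exactly 1:
#' `prev * rr_any_prev * RR + (1 - prev) * RR = 1`.
#'
#' @param rr_any_prev Risk ratio (any fracture) of women with versus without a
#'   previous fracture (> 0).
#' @param prev Prevalence of a previous fracture, in \[0, 1\].
#' @return Relative risk versus the general population; in (0, 1] whenever
#'   `rr_any_prev >= 1`.
#' @export
#' @examples
#' rr_no_previous_fracture(2.0, 0.25) # 0.8
rr_no_previous_fracture <- function(rr_any_prev, prev) {
  if (any(rr_any_prev <= 0)) stop("rr_any_prev must be > 0")
  if (any(prev < 0) || any(prev > 1)) stop("prev must lie in [0, 1]")
  1 / (1 + (rr_any_prev - 1) * prev)
}

#' Annual fracture probability adjusted for fracture history
#'
#' Multiplies the general-population probability by the no-previous-fracture
#' calibration factor, and additionally by the type-specific previous-fracture
#' risk ratio when the woman has a fracture history (hip uses the hip-specific
#' ratio, the five other sites the pooled osteoporotic-fracture ratio).
#'
#' @param p_general General-population annual fracture probability.
#' @param rr_no_prev Relative risk of the no-previous-fracture subgroup versus
#'   the general population (see [rr_no_previous_fracture()]).
#' @param rr_prev_given_type Risk ratio with-versus-without previous fracture
#'   for this fracture type.
#' @param has_previous Logical; does the woman have a previous fracture?
#' @return Annual probability, clipped to at most 1 with a warning.
#' @export
#' @examples
#' fracture_prob_by_history(0.01, 0.8, 2.0, TRUE)  # 0.016
#' fracture_prob_by_history(0.01, 0.8, 2.0, FALSE) # 0.008
fracture_prob_by_history <- function(p_general, rr_no_prev,
                                     rr_prev_given_type, has_previous) {
  p <- p_general * rr_no_prev * ifelse(has_previous, rr_prev_given_type, 1)
  if (any(p > 1)) {
    warning(sum(p > 1), " history-adjusted probabilities clipped to 1")
    p <- pmin(p, 1)
  }
  p
}

#' Relative fracture risk of osteoporotic women versus the general population
#'
#' Under the standard BMD gradient-of-risk model, femoral-neck T-scores in an
#' age class follow `T ~ Normal(mean_tscore, 1)` and fracture risk is
#' proportional to `gradient^(-T)`, where `gradient` is the relative risk per
#' one standard deviation decrease in BMD. The mean risk among women below the
#' osteoporosis threshold (`T <= threshold`) relative to the whole population
#' has the closed form
#' `pnorm(threshold - mean_tscore + log(gradient)) / pnorm(threshold - mean_tscore)`.
#'
#' @param gradient Relative risk per 1-SD decrease in BMD (>= 1).
#' @param mean_tscore Population mean femoral-neck T-score of the age class.
#' @param threshold Osteoporosis T-score threshold (default -2.5).
#' @return Relative risk (>= 1).
#' @export
#' @examples
#' rr_osteoporotic(2.0, 0.0, -2.5) # about 5.70
rr_osteoporotic <- function(gradient, mean_tscore, threshold = -2.5) {
  if (any(gradient < 1)) stop("gradient must be >= 1")
  z <- threshold - mean_tscore
  denom <- stats::pnorm(z)
  if (any(denom < 1e-12)) {
    stop("osteoporosis prevalence underflow: threshold lies far below the ",
         "mean T-score; use a coarser age class or override the prevalence")
  }
  stats::pnorm(z + log(gradient)) / denom
}

#' Relative fracture risk of non-osteoporotic women
#'
#' Consistency split of the population risk: given the osteoporotic subgroup's
#' relative risk and the osteoporosis prevalence, the non-osteoporotic
#' subgroup's relative risk versus the general population is
#' `(1 - prevalence * rr_ost) / (1 - prevalence)`, so that
#' `prevalence * rr_ost + (1 - prevalence) * result = 1` holds exactly.
#'
#' @param rr_ost Relative risk of the osteoporotic subgroup.
#' @param prevalence Osteoporosis prevalence, in \[0, 1).
#' @return Relative risk of the non-osteoporotic subgroup.
#' @export
#' @examples
#' rr_non_osteoporotic(4.0, 0.2) # 0.25
rr_non_osteoporotic <- function(rr_ost, prevalence) {
  if (any(prevalence < 0) || any(prevalence >= 1)) {
    stop("prevalence must lie in [0, 1)")
  }
  if (any(rr_ost * prevalence >= 1)) {
    stop("inconsistent inputs: rr_ost * prevalence must be < 1")
  }
  (1 - prevalence * rr_ost) / (1 - prevalence)
}

#' Convert a prevalence step into an annual transition probability
#'
#' For an irreversible condition, the annual incidence probability that takes a
#' cohort from prevalence `p_low` to `p_high` over `span_years` years (ignoring
#' differential mortality) is
#' `q = 1 - ((1 - p_high) / (1 - p_low))^(1 / span_years)`.
#' Applying `q` for `span_years` years to a cohort starting at `p_low`
#' reproduces `p_high` exactly. Used for osteoporosis onset and for background
#' nursing-home entry derived from care prevalence.
#'
#' @param p_low,p_high Prevalences at the start and end of the span, with
#'   `p_low <= p_high < 1` (the condition is irreversible).
#' @param span_years Length of the span in years (> 0).
#' @param floor_negative If `TRUE`, a prevalence decrease yields `q = 0`
#'   instead of an error.
#' @return Annual transition probability.
#' @export
#' @examples
#' prevalence_to_incidence(0.0, 0.2, 5) # about 0.04365
prevalence_to_incidence <- function(p_low, p_high, span_years,
                                    floor_negative = FALSE) {
  if (any(span_years <= 0)) stop("span_years must be > 0")
  if (any(p_high >= 1) || any(p_low < 0)) {
    stop("prevalences must lie in [0, 1)")
  }
  if (any(p_high < p_low)) {
    if (!floor_negative) {
      stop("p_high < p_low violates irreversibility; ",
           "use floor_negative = TRUE to floor the probability at 0")
    }
  }
  q <- 1 - ((1 - p_high) / (1 - p_low))^(1 / span_years)
  pmax(q, 0)
}
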