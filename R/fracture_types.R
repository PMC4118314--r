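#' Fracture types tracked by the model
#'
#' The six osteoporotic fracture sites, in the fixed order used everywhere in
#' the package. The ordering is load-bearing: each type owns fixed
#' random-number slots (see [crn_uniform()]), so a stable order is required for
#' reproducibility and for common-random-number pairing.
#'
#' @return Character vector of length six:
#'   `hip`, `other_femur`, `clinical_vertebral`, `humerus`, `pelvis`, `wrist`.
#' @export
#' @examples
#' fracture_types()
fracture_types <- function() {
  c("hip", "other_femur", "clinical_vertebral", "humerus", "pelvis", "wrist")
}

N_FRACTURE_TYPES <- 6L

#' Five-year age-class labels covering ages 50 to 100
#'
#' Bands `50-54` through `90-94` plus the open band `95+`. Every integer age
#' in 50..100 maps to exactly one band; lookups are piecewise constant (no
#' interpolation between bands), matching how the published inputs are
#' tabulated.
#'
#' @return Character vector of the ten band labels.
#' @export
age_classes <- function() {
  c("50-54", "55-59", "60-64", "65-69", "70-74",
    "75-79", "80-84", "85-89", "90-94", "95+")
}

#' Map integer ages to age-class indices
#'
#' @param age Integer vector of ages in 50..100.
#' @return Integer vector of indices into [age_classes()].
#' @export
#' @examples
#' age_classes()[age_class_index(c(50, 67, 95, 100))]
age_class_index <- function(age) {
  if (any(age < 50 | age > 100)) {
    stop("ages must lie in [50, 100]")
  }
  pmin((age - 50L) %/% 5L + 1L, 10L)
}

#' Validate an age-class schedule
#'
#' A schedule is a numeric vector with one finite value per age class, named
#' by [age_classes()]. Used for all banded inputs (fracture probabilities,
#' prevalences, mean T-scores, ...).
#'
#' @param x Numeric vector to check.
#' @param what Label used in error messages.
#' @param lower,upper Optional inclusive bounds.
#' @return `x`, invisibly, with names normalised to [age_classes()].
#' @keywords internal
check_schedule <- function(x, what, lower = -Inf, upper = Inf) {
  if (length(x) != 10L || !is.numeric(x)) {
    stop(what, ": expected one numeric value per age class (10 values)")
  }
  if (any(!is.finite(x))) stop(what, ": all values must be finite")
  if (any(x < lower) || any(x > upper)) {
    stop(sprintf("%s: values must lie in [%g, %g]", what, lower, upper))
  }
  names(x) <- age_classes()
  invisible(x)
}
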