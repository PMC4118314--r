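# Common-random-number (CRN) machinery.
#
# Every stochastic decision in the simulation reads a uniform draw addressed
# by (master seed, person index, interval, decision slot). The draw depends on
# nothing else -- not the risk group, not the parameter values, not which
# other decisions were evaluated -- so two runs that share a seed are coupled
# person by person and decision by decision. This is what makes paired
# excess-cost estimation and the zero-excess identity exact.

# fixed decision-slot order within a person-year
SLOT_OSTEO_ONSET <- 1L
SLOT_FRACTURE <- 2:7       # one per fracture type, in fracture_types() order
SLOT_HOSPITAL <- 8:13
SLOT_REHAB <- 14:19
SLOT_NH_FRACTURE <- 20L
SLOT_NH_BACKGROUND <- 21L
SLOT_NH_COUNTERFACTUAL <- 22L
SLOT_SURVIVAL <- 23L
N_SLOTS <- 23L

# interval index 0 is reserved for the preload draws
SLOT_PRELOAD_OSTEO <- 1L
SLOT_PRELOAD_PREVFX <- 2L

crn_subseed <- function(seed, year, slot) {
  if (seed < 0 || seed >= 2^31) stop("seed must be a nonnegative 32-bit integer")
  base <- (as.numeric(seed) %% 65011) * 33029
  (base + year * 31 + slot) %% 2147483647
}

#' Uniform draws for one decision slot of one simulated year
#'
#' Returns the uniforms for persons `1..n` at interval `year` (0 = preload)
#' and decision slot `slot`. The value for person `i` is a pure function of
#' `(seed, i, year, slot)`; in particular it does not depend on `n`, on the
#' risk group, or on any model parameter. The caller's RNG state is left
#' untouched.
#'
#' @param seed Master seed (nonnegative integer below 2^31).
#' @param n Number of persons.
#' @param year Interval index (0 for preload, then 1, 2, ...).
#' @param slot Decision slot index.
#' @return Numeric vector of `n` uniforms.
#' @export
crn_uniform <- function(seed, n, year, slot) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(crn_subseed(seed, year, slot), kind = "Mersenne-Twister")
  stats::runif(n)
}

# scalar access for the per-person reference engine; O(person_index)
crn_uniform1 <- function(seed, person_index, year, slot) {
  crn_uniform(seed, person_index, year, slot)[person_index]
}
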