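#' Define a start-characteristic scenario
#'
#' A scenario fixes the four start characteristics of the simulated woman:
#' start age (50 or 75), residence (community `C` or nursing home `N`),
#' disease status (`O` already osteoporotic, `avO` average risk, `nO` never
#' osteoporotic), and fracture history (`P` previous fracture, `nP` none).
#' Nursing-home residence requires a start age of at least 65, which leaves
#' exactly 18 valid combinations (see [all_scenarios()]).
#'
#' @param start_age 50 or 75.
#' @param residence `"C"` or `"N"`.
#' @param disease `"O"`, `"avO"` or `"nO"`.
#' @param history `"P"` or `"nP"`, or `"prevalence"` to draw the
#'   previous-fracture flag from the age-specific prevalence (the base case).
#' @return A `scenario_spec` with a label such as `50_C_avO_nP`.
#' @export
#' @examples
#' scenario_spec(50, "C", "avO", "nP")
scenario_spec <- function(start_age = 50, residence = c("C", "N"),
                          disease = c("avO", "O", "nO"),
                          history = c("prevalence", "P", "nP")) {
  residence <- match.arg(residence)
  disease <- match.arg(disease)
  history <- match.arg(history)
  if (!start_age %in% c(50, 75)) stop("start_age must be 50 or 75")
  if (residence == "N" && start_age < 65) {
    stop("nursing-home residence requires a start age of at least 65")
  }
  hist_lab <- if (history == "prevalence") "avP" else history
  spec <- list(start_age = as.integer(start_age), residence = residence,
               disease = disease, history = history,
               label = paste(start_age, residence, disease, hist_lab,
                             sep = "_"))
  class(spec) <- "scenario_spec"
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario>", x$label, "\n")
  invisible(x)
}

#' All 18 valid start-characteristic scenarios
#'
#' The full cross of age {50, 75}, residence {C, N}, disease {O, avO, nO} and
#' history {P, nP}, minus the invalid nursing-home-at-50 combinations.
#'
#' @return Named list of 18 `scenario_spec` objects.
#' @export
all_scenarios <- function() {
  out <- list()
  for (age in c(50, 75)) {
    for (res in c("C", "N")) {
      if (res == "N" && age < 65) next
      for (dis in c("O", "avO", "nO")) {
        for (his in c("P", "nP")) {
          s <- scenario_spec(age, res, dis, his)
          out[[s$label]] <- s
        }
      }
    }
  }
  out
}
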