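#' Hormone scenarios
#'
#' A hormone scenario fixes the concentrations of estrogen and progesterone
#' (pM) and testosterone (nM) applied, constant in time, to a simulation.
#' An all-zero scenario disables every hormone feedback term (each hormone
#' multiplier evaluates to its zero-concentration value).
#'
#' @param estrogen estradiol concentration, pM.
#' @param progesterone progesterone concentration, pM.
#' @param testosterone testosterone concentration, nM.
#' @return An object of class \code{hormone_scenario}.
#' @export
#' @examples
#' hormone_scenario(estrogen = 143)
#' isolated_scenarios()
hormone_scenario <- function(estrogen = 0, progesterone = 0,
                             testosterone = 0) {
  if (estrogen < 0 || progesterone < 0 || testosterone < 0)
    stop("hormone concentrations must be non-negative")
  structure(list(estrogen = estrogen, progesterone = progesterone,
                 testosterone = testosterone),
            class = "hormone_scenario")
}

#' @export
print.hormone_scenario <- function(x, ...) {
  cat(sprintf("Hormone scenario: E2 = %g pM, P4 = %g pM, T = %g nM\n",
              x$estrogen, x$progesterone, x$testosterone))
  invisible(x)
}

# scenario concentration of a hormone id, in that hormone's native unit
# (pM for E2/P4, nM for T)
.hormone_value <- function(scenario, id) {
  switch(id,
         E2 = scenario$estrogen,
         P4 = scenario$progesterone,
         T = scenario$testosterone,
         stop("unknown hormone id: ", id))
}

.hormone_native_unit <- function(id) {
  switch(id, E2 = "pM", P4 = "pM", T = "nM",
         stop("unknown hormone id: ", id))
}

#' The three isolated-hormone scenarios
#'
#' Single-hormone conditions at representative physiological
#' concentrations: estrogen alone at 143 pM (early follicular phase),
#' estrogen plus progesterone (143 pM and 990 pM), and testosterone alone
#' at 20 nM (adult male range).
#'
#' @return Named list of \code{\link{hormone_scenario}} objects with
#'   elements \code{E_only}, \code{E_plus_P}, \code{T_only}.
#' @export
isolated_scenarios <- function() {
  list(
    E_only = hormone_scenario(estrogen = 143),
    E_plus_P = hormone_scenario(estrogen = 143, progesterone = 990),
    T_only = hormone_scenario(testosterone = 20)
  )
}

#' Physiological estrogen/testosterone ranges by condition
#'
#' Serum ranges for an adult male, a female in the early follicular phase
#' ("female_low_e") and a female around the ovulatory estrogen peak
#' ("female_peak_e").  Progesterone is zero in all three combined-hormone
#' conditions.
#'
#' @param condition one of \code{"male"}, \code{"female_low_e"},
#'   \code{"female_peak_e"}.
#' @return List with elements \code{estrogen} (pM, length-2 range) and
#'   \code{testosterone} (nM, length-2 range).
#' @export
condition_ranges <- function(condition) {
  switch(condition,
         male = list(estrogen = c(1.0, 106), testosterone = c(8.7, 38.1)),
         female_low_e = list(estrogen = c(143, 673),
                             testosterone = c(0.069, 1.38)),
         female_peak_e = list(estrogen = c(2266, 2797),
                              testosterone = c(0.069, 1.38)),
         stop("unknown hormone condition: '", condition,
              "' (expected male, female_low_e or female_peak_e)"))
}

#' Latin hypercube draws of hormone concentrations for a condition
#'
#' Estrogen and testosterone are sampled with the same row-permutation
#' Latin hypercube scheme used for model coefficients: each hormone's
#' marginal is an evenly spaced grid spanning its physiological range,
#' independently permuted.  Progesterone is 0.
#'
#' @param condition condition name, see \code{\link{condition_ranges}}.
#' @param n number of draws (>= 1).
#' @param seed integer seed for the permutation generator.
#' @return List of \code{n} \code{\link{hormone_scenario}} objects.
#' @export
#' @examples
#' sample_condition("male", n = 3, seed = 1)
sample_condition <- function(condition, n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  rng <- condition_ranges(condition)
  grid <- lhs_range_matrix(rbind(estrogen = rng$estrogen,
                                 testosterone = rng$testosterone),
                           n, seed = seed)
  lapply(seq_len(n), function(i)
    hormone_scenario(estrogen = grid["estrogen", i],
                     testosterone = grid["testosterone", i]))
}
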