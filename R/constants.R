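#' Physical constants and unit conversions
#'
#' `kB` is the Boltzmann constant in kcal mol^-1 K^-1, the unit system used
#' throughout: distances in Angstrom, energies in kcal/mol, temperatures in K,
#' ionic strengths in mol/dm^3. Heat capacities are reported in
#' cal mol^-1 K^-1 (the conventional unit for excess heat capacities of
#' association); `kcalToCal()` is the single conversion point.
#'
#' @format `kB` is a length-one numeric, 0.0019872041 kcal mol^-1 K^-1.
#' @export
kB <- 0.0019872041

#' @rdname kB
#' @param x energy (or energy-derived) quantity in kcal-based units
#' @return `x` converted from kcal- to cal-based units.
#' @export
kcalToCal <- function(x) x * 1000
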