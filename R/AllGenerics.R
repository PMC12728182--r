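#' Ordered state labels of an exchange scheme
#' @param object an \linkS4class{ExchangeScheme}
#' @return character vector, free state first
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))

#' Number of states in an exchange scheme
#' @param object an \linkS4class{ExchangeScheme}
#' @return integer state count
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' Per-step equilibrium constants of the folding chain
#'
#' K_eq,AB = kAB/kBA = pB/pA and K_eq,BC = kBC/kCB = pC/pB; consistent with
#' the stored microscopic rates by construction.
#' @param object an \linkS4class{ExchangeScheme}
#' @return named numeric vector, one entry per subsequent step
#' @export
setGeneric("keq", function(object) standardGeneric("keq"))

#' Per-step exchange rates (k_fwd + k_rev)
#' @param object an \linkS4class{ExchangeScheme}
#' @return named numeric vector, one entry per subsequent step
#' @export
setGeneric("kex", function(object) standardGeneric("kex"))

#' Fractional state populations
#' @param object a \linkS4class{StatePopulations}
#' @return named numeric vector summing to 1
#' @export
setGeneric("populations", function(object) standardGeneric("populations"))

#' Best-fit global exchange parameters
#' @param object a \linkS4class{GlobalFitResult}
#' @return named numeric vector
#' @export
setGeneric("globalParams", function(object) standardGeneric("globalParams"))

#' Total masked chi-square of a fit
#' @param object a \linkS4class{GlobalFitResult}
#' @return numeric chi-square
#' @export
setGeneric("chiSquare", function(object) standardGeneric("chiSquare"))

#' Residue-specific best-fit parameters
#' @param object a \linkS4class{GlobalFitResult}
#' @return data.frame, one row per residue
#' @export
setGeneric("residueParams", function(object) standardGeneric("residueParams"))

#' Per-temperature thermodynamic table
#' @param object a \linkS4class{ThermoTable}
#' @return data.frame with columns T_K, Kd_uM, dG_kJ, dH_kJ, dS_J, TdS_kJ
#' @export
setGeneric("thermoData", function(object) standardGeneric("thermoData"))
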