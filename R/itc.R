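# Isothermal titration calorimetry: one-set-of-sites model for concatenated
# injection series, per-temperature thermodynamics (heat capacity, Kd
# extrapolation, iso-entropic temperature) and the Spolar-Record entropy
# decomposition with folded-residue estimation.
#
# Units: concentrations uM, volumes uL, heats uJ, enthalpies kJ/mol,
# entropies J/mol/K. Standard state for dG is 1 M.

GAS_CONSTANT <- 8.314       # J mol-1 K-1
SR_REFERENCE_T <- 386       # K, reference temperature of the conformational-
                            # entropy parameterization
SR_DS_RT <- -110            # J mol-1 K-1, rotational/translational entropy

#' Construct an ITC injection series
#'
#' @param temperature experiment temperature (K)
#' @param cellVolume calorimeter cell volume (uL)
#' @param cellConc initial macromolecule concentration in the cell (uM)
#' @param syringeConc titrant concentration in the syringe (uM)
#' @param volumes per-injection volumes (uL)
#' @param heats per-injection integrated heats (uJ)
#' @param segments segment id per injection marking syringe-refill
#'   concatenation boundaries (cell content is continuous across segments)
#' @return an \linkS4class{InjectionSeries}
#' @export
InjectionSeries <- function(temperature, cellVolume, cellConc, syringeConc,
                            volumes, heats, segments = rep(1L, length(volumes))) {
  new("InjectionSeries", temperature = temperature, cellVolume = cellVolume,
      cellConc = cellConc, syringeConc = syringeConc, volumes = volumes,
      heats = heats, segments = as.integer(segments))
}

setMethod("show", "InjectionSeries", function(object) {
  cat(sprintf("ITC series: %d injections (%d segments) at %.2f K; cell %.4g uM, syringe %.4g uM\n",
              length(object@volumes), length(unique(object@segments)),
              object@temperature, object@cellConc, object@syringeConc))
  invisible(NULL)
})

#' Predicted per-injection heats of the one-set-of-sites model
#'
#' Standard perfusion-cell displacement model: each injection of volume dV
#' dilutes both species by (1 - dV/V0) while titrant accumulates from the
#' syringe. The bound complex after each injection is the physical root of
#' the single-site quadratic with n equivalent sites; the injection heat is
#' \deqn{q_i = \Delta H \, V_0 \, (B_i - B_{i-1}(1 - dV_i/V_0)) + q_{offset}}
#' (the subtracted term is complex displaced from the cell). Concatenated
#' segments share one parameter set; the cell content carries across refills.
#'
#' @param fit an \linkS4class{OneSiteFit} (or a named list/vector with n, Kd,
#'   dH, qOffset)
#' @param series an \linkS4class{InjectionSeries}
#' @return numeric vector of per-injection heats (uJ)
#' @export
oneSiteHeats <- function(fit, series) {
  if (is(fit, "OneSiteFit"))
    fit <- c(n = fit@n, Kd = fit@Kd, dH = fit@dH, qOffset = fit@qOffset)
  n <- fit[["n"]]; Kd <- fit[["Kd"]]; dH <- fit[["dH"]]
  q0 <- if ("qOffset" %in% names(fit)) fit[["qOffset"]] else 0
  V0 <- series@cellVolume
  if (series@syringeConc <= 0) stop("syringe concentration must be > 0")
  M <- series@cellConc       # macromolecule (cell), uM
  X <- 0                     # titrant, uM
  Bprev <- 0                 # complex, uM
  q <- numeric(length(series@volumes))
  for (i in seq_along(series@volumes)) {
    dil <- 1 - series@volumes[i] / V0
    M <- M * dil
    X <- X * dil + series@syringeConc * series@volumes[i] / V0
    # smaller root of B^2 - B(nM + X + Kd) + nM X = 0
    b <- n * M + X + Kd
    B <- 2 * n * M * X / (b + sqrt(b^2 - 4 * n * M * X))
    # kJ/mol * uL * uM = 1e-3 uJ
    q[i] <- dH * V0 * (B - Bprev * dil) * 1e-3 + q0
    Bprev <- B
  }
  q
}

#' Fit the one-set-of-sites model to an injection series
#'
#' Least-squares fit of (n, Kd, dH, qOffset) to the concatenated injection
#' heats by bounded Levenberg-Marquardt. Kd is optimized on a log10 scale.
#'
#' @param series an \linkS4class{InjectionSeries}
#' @param init named initial values (n, Kd, dH, qOffset); sensible defaults
#'   are derived from the series when omitted
#' @param excludeFirst drop the first injection of each segment from the
#'   residuals (classic ITC practice; default FALSE, the offset term absorbs
#'   small systematic heats instead)
#' @return a \linkS4class{OneSiteFit}
#' @export
fitOneSite <- function(series, init = NULL, excludeFirst = FALSE) {
  if (length(series@volumes) < 10) stop("need at least 10 injections")
  heats <- series@heats
  use <- rep(TRUE, length(heats))
  if (excludeFirst) use[match(unique(series@segments), series@segments)] <- FALSE
  if (max(abs(heats[use])) < .Machine$double.eps^0.5) {
    return(new("OneSiteFit", n = 1, Kd = 1, dH = 0, qOffset = 0,
               se = c(n = NA_real_, Kd = NA_real_, dH = NA_real_, qOffset = NA_real_),
               converged = FALSE, flagged = TRUE))
  }
  if (is.null(init)) {
    # total heat -> dH scale; mid-curve Kd guess at cell concentration / 5
    dH0 <- sum(heats[use]) / (series@cellConc * series@cellVolume * 1e-3)
    init <- c(n = 1, Kd = max(series@cellConc / 5, 1), dH = dH0, qOffset = 0)
  }
  par0 <- c(n = unname(init[["n"]]), logKd = log10(unname(init[["Kd"]])),
            dH = unname(init[["dH"]]), qOffset = unname(init[["qOffset"]]))
  fn <- function(p) {
    q <- oneSiteHeats(c(n = p[["n"]], Kd = 10^p[["logKd"]], dH = p[["dH"]],
                        qOffset = p[["qOffset"]]), series)
    (heats - q)[use]
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = fn,
                            lower = c(n = 0.05, logKd = -3, dH = -1e4, qOffset = -1e5),
                            upper = c(n = 20, logKd = 6, dH = 1e4, qOffset = 1e5),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  se <- tryCatch(sqrt(diag(solve(fit$hessian)) * fit$deviance /
                        (sum(use) - length(p))),
                 error = function(e) rep(NA_real_, length(p)))
  names(se) <- c("n", "logKd", "dH", "qOffset")
  seOut <- c(n = se[["n"]], Kd = log(10) * 10^p[["logKd"]] * se[["logKd"]],
             dH = se[["dH"]], qOffset = se[["qOffset"]])
  new("OneSiteFit", n = p[["n"]], Kd = 10^p[["logKd"]], dH = p[["dH"]],
      qOffset = p[["qOffset"]], se = seOut,
      converged = fit$info %in% c(1, 2, 3, 4), flagged = FALSE)
}

setMethod("show", "OneSiteFit", function(object) {
  cat(sprintf("One-set-of-sites fit: n = %.3f, Kd = %.4g uM, dH = %.4g kJ/mol, offset = %.3g uJ%s\n",
              object@n, object@Kd, object@dH, object@qOffset,
              if (object@flagged) " [FLAGGED]" else ""))
  invisible(NULL)
})

#' Wiseman c-parameter of a titration design
#'
#' c = n [cell] / Kd, the dimensionless isotherm shape parameter.
#' @param n stoichiometry
#' @param cellConc cell concentration (uM)
#' @param Kd dissociation constant (uM)
#' @export
wisemanC <- function(n, cellConc, Kd) n * cellConc / Kd

#' Gibbs free energy of binding from a dissociation constant
#'
#' dG = R T ln(Kd / 1 M), 1 M standard state.
#' @param Kd dissociation constant (uM)
#' @param T temperature (K)
#' @return dG in kJ/mol
#' @export
gibbs <- function(Kd, T) {
  if (any(Kd <= 0)) stop("Kd must be > 0")
  GAS_CONSTANT * T * log(Kd * 1e-6) / 1000
}

#' Assemble a per-temperature thermodynamic table
#'
#' Computes dG = RT ln(Kd), dS = (dH - dG)/T and -TdS for each temperature's
#' one-site fit; the identities dG = dH - T dS and dG = RT ln(Kd/1M) hold
#' per row by construction.
#'
#' @param temperatures temperatures (K)
#' @param Kd per-temperature dissociation constants (uM)
#' @param dH per-temperature binding enthalpies (kJ/mol)
#' @return a \linkS4class{ThermoTable}
#' @export
ThermoTable <- function(temperatures, Kd, dH) {
  dG <- gibbs(Kd, temperatures)
  dS <- (dH - dG) / temperatures * 1000   # J/mol/K
  new("ThermoTable", table = data.frame(
    T_K = temperatures, Kd_uM = Kd, dG_kJ = dG, dH_kJ = dH, dS_J = dS,
    TdS_kJ = temperatures * dS / 1000))
}

#' @rdname thermoData
#' @export
setMethod("thermoData", "ThermoTable", function(object) object@table)

setMethod("show", "ThermoTable", function(object) {
  cat("Per-temperature binding thermodynamics:\n")
  print(format(object@table, digits = 4), row.names = FALSE)
  invisible(NULL)
})

#' Heat-capacity change of binding
#'
#' Slope of the linear least-squares fit of dH versus T.
#' @param table a \linkS4class{ThermoTable} with >= 3 temperatures
#' @return dCp in kJ mol-1 K-1
#' @export
heatCapacity <- function(table) {
  tab <- thermoData(table)
  if (nrow(tab) < 3) stop("need at least 3 temperatures")
  unname(coef(lm(dH_kJ ~ T_K, tab))[2])
}

#' Extrapolate the dissociation constant to a target temperature
#'
#' Linear least squares of dG versus T, inverted at the target temperature;
#' the route used when dH ~ 0 makes a direct isotherm fit at that
#' temperature ill-conditioned.
#'
#' @param table a \linkS4class{ThermoTable} with >= 3 temperatures
#' @param Ttarget target temperature (K)
#' @return Kd in uM
#' @export
extrapolateKd <- function(table, Ttarget) {
  tab <- thermoData(table)
  if (nrow(tab) < 3) stop("need at least 3 temperatures")
  cf <- coef(lm(dG_kJ ~ T_K, tab))
  dG <- unname(cf[1] + cf[2] * Ttarget)
  exp(dG * 1000 / (GAS_CONSTANT * Ttarget)) * 1e6
}

#' Iso-entropic temperature
#'
#' Zero crossing of the linear least-squares fit of dS versus T: the
#' temperature at which the total binding entropy vanishes.
#'
#' @param table a \linkS4class{ThermoTable}
#' @return T_S in K; NA with a warning if dS does not change with T
#' @export
isoEntropicTemp <- function(table) {
  tab <- thermoData(table)
  if (nrow(tab) < 2) stop("need at least 2 temperatures")
  cf <- coef(lm(dS_J ~ T_K, tab))
  if (!is.finite(cf[2]) || abs(cf[2]) < 1e-12) {
    warning("dS does not vary with temperature: T_S undefined")
    return(NA_real_)
  }
  unname(-cf[1] / cf[2])
}

#' Spolar-Record entropy decomposition
#'
#' Partitions the binding entropy at temperature T into conformational,
#' desolvation and rotational/translational contributions:
#' \deqn{\Delta S(T) = \Delta S_{conf} + \Delta S_{desolv}(T) + \Delta S_{rt}}
#' with the empirical IDP-complex parameterization
#' \deqn{\Delta S^\circ_{conf} = -1.66\,\Delta C_p \ln(T_S/386\,K) + 110\ \mathrm{J\,mol^{-1}K^{-1}}}
#' \deqn{\Delta S_{desolv}(T) = 1.66\,\Delta C_p \ln(T/386\,K)}
#' and the constant \eqn{\Delta S_{rt} = -110} J/mol/K. By construction the
#' total vanishes at T = T_S. Dividing the conformational term by an average
#' per-residue entropy loss estimates how many residues fold upon binding.
#'
#' @param dCp heat-capacity change (kJ mol-1 K-1; converted internally)
#' @param TS iso-entropic temperature (K)
#' @param T evaluation temperature (K)
#' @param perResidue assumed per-residue conformational entropy loss
#'   (J mol-1 K-1, negative)
#' @return an \linkS4class{EntropyDecomposition}
#' @export
spolarRecord <- function(dCp, TS, T = 298.15, perResidue = -24) {
  if (!is.finite(dCp)) stop("dCp must be finite")
  if (TS <= 0 || T <= 0) stop("temperatures must be > 0")
  dCpJ <- dCp * 1000
  dSconf <- -1.66 * dCpJ * log(TS / SR_REFERENCE_T) + 110
  dSdesolv <- 1.66 * dCpJ * log(T / SR_REFERENCE_T)
  total <- dSconf + dSdesolv + SR_DS_RT
  new("EntropyDecomposition", T = T, dSTotal = total, dSConf = dSconf,
      dSDesolv = dSdesolv, dSrt = SR_DS_RT, TS = TS, dCp = dCp,
      perResidue = perResidue,
      foldedResidues = foldedResidueCount(dSconf, perResidue))
}

#' Number of residues folding upon binding
#'
#' @param dSconf conformational entropy change (J mol-1 K-1)
#' @param perResidue per-residue conformational entropy loss (J mol-1 K-1,
#'   must be negative)
#' @return rounded residue count
#' @export
foldedResidueCount <- function(dSconf, perResidue = -24) {
  if (perResidue >= 0) stop("perResidue must be negative")
  round(dSconf / perResidue)
}

setMethod("show", "EntropyDecomposition", function(object) {
  cat(sprintf("Entropy decomposition at %.2f K (T_S = %.2f K, dCp = %.3g kJ/mol/K):\n",
              object@T, object@TS, object@dCp))
  cat(sprintf("  dS_conf     = %8.1f J/mol/K\n", object@dSConf))
  cat(sprintf("  dS_desolv   = %8.1f J/mol/K\n", object@dSDesolv))
  cat(sprintf("  dS_rt       = %8.1f J/mol/K\n", object@dSrt))
  cat(sprintf("  dS_total    = %8.1f J/mol/K\n", object@dSTotal))
  cat(sprintf("  ~%d residues fold upon binding (at %.0f J/mol/K per residue)\n",
              object@foldedResidues, object@perResidue))
  invisible(NULL)
})
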