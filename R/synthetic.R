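# Synthetic-data generation: CEST datasets, relaxation decays and ITC
# titration series with the statistical structure the analysis stages
# assume, plus the ground truth needed for parameter-recovery validation.

#' Default CEST experiment grid
#'
#' Three D-CEST experiments (B1 = 5.2, 10.3, 20.5 Hz with DANTE windows of
#' 240, 448 and 800 Hz, offsets stepped by 8, 16 and 32 Hz across one
#' window) and one continuous-wave experiment (B1 = 68.6 Hz, offsets stepped
#' by 100 Hz across 103-134 ppm), all with a 0.4 s saturation period.
#'
#' @param larmor15N 15N Larmor frequency (MHz)
#' @param carrier carrier position (ppm)
#' @param Tsat saturation period (s)
#' @return list of \linkS4class{CestExperiment}
#' @export
defaultExperiments <- function(larmor15N = 96.3, carrier = 118.5, Tsat = 0.4) {
  dante <- mapply(function(b1, win, step) {
    half <- floor((win / 2) / step) * step
    CestExperiment(B1 = b1, Tsat = Tsat, irradiation = "dante",
                   danteWindow = win, larmor15N = larmor15N, carrier = carrier,
                   offsets = seq(-half, half, by = step))
  }, c(5.2, 10.3, 20.5), c(240, 448, 800), c(8, 16, 32), SIMPLIFY = FALSE)
  lo <- (103 - carrier) * larmor15N
  hi <- (134 - carrier) * larmor15N
  cw <- CestExperiment(B1 = 68.6, Tsat = Tsat, irradiation = "cw",
                       larmor15N = larmor15N, carrier = carrier,
                       offsets = seq(lo, hi, by = 100))
  c(dante, list(cw))
}

#' The reference exchange parameters used as synthetic ground truth
#'
#' The globally fitted rate constants of the hierarchical binding scheme:
#' kon = 7.3e5 M-1 s-1, koff = 56 s-1, kAB = 72, kBA = 64, kBC = 89,
#' kCB = 94 s-1.
#' @return an \linkS4class{ExchangeScheme}
#' @export
referenceScheme <- function() {
  ExchangeScheme("4site", kon = 7.3e5, koff = 56, kAB = 72, kBA = 64,
                 kBC = 89, kCB = 94)
}

#' Build the default ground-truth scenario
#'
#' Residue classes emulate the shift-difference structure of hierarchical
#' folding-upon-binding:
#' \itemize{
#'   \item \strong{crib} (anchoring motif): |dwFA| drawn in [1, 4] ppm, already
#'     shifted in intermediate A; dwFB = dwFA; dwFC near dwFB.
#'   \item \strong{mre1_helix}: dwFA = 0, |dwFB| in [1, 5] ppm (folds in B),
#'     dwFC near dwFB.
#'   \item \strong{mre2}: dwFA = 0, dwFB = f dwFC with f in (0.2, 0.8)
#'     (partially shifted in B, between free and fully bound), |dwFC| in
#'     [1, 6] ppm.
#'   \item \strong{linker}: all dw ~ 0.
#' }
#' Default roster: anchoring residues 325, 327, 330, 331 and 333, three
#' helix residues, three hairpin residues and one linker residue (12 total).
#'
#' @param seed RNG seed (scenario draws are fully reproducible)
#' @param sigma intensity noise as a fraction of the reference intensity
#' @param cribResidues,mre1Residues,mre2Residues,linkerResidues residue ids
#'   per class (shrink for fast tests)
#' @param experiments list of \linkS4class{CestExperiment}
#' @param scheme true \linkS4class{ExchangeScheme}
#' @param composition true \linkS4class{MixtureComposition}
#' @return a \linkS4class{GroundTruthScenario}
#' @export
makeDefaultScenario <- function(seed = 1, sigma = 0.004,
                                cribResidues = c(325L, 327L, 330L, 331L, 333L),
                                mre1Residues = c(340L, 343L, 347L),
                                mre2Residues = c(358L, 362L, 366L),
                                linkerResidues = 352L,
                                experiments = defaultExperiments(),
                                scheme = referenceScheme(),
                                composition = MixtureComposition(500, 100, 24)) {
  set.seed(seed)
  ids <- c(cribResidues, mre1Residues, mre2Residues, linkerResidues)
  cls <- rep(c("crib", "mre1_helix", "mre2", "linker"),
             c(length(cribResidues), length(mre1Residues),
               length(mre2Residues), length(linkerResidues)))
  n <- length(ids)
  roster <- data.frame(residueId = ids, class = cls,
                       shiftF = runif(n, 108, 126),
                       dwFA = 0, dwFB = 0, dwFC = 0,
                       R1F = runif(n, 1.0, 2.0), R2F = runif(n, 3, 8),
                       R2B = runif(n, 15, 35), R2C = NA_real_)
  roster$R2C <- roster$R2B * runif(n, 0.8, 1.25)
  sgn <- function(m) sample(c(-1, 1), m, replace = TRUE)
  for (i in seq_len(n)) {
    if (cls[i] == "crib") {
      roster$dwFA[i] <- sgn(1) * runif(1, 1, 4)
      roster$dwFB[i] <- roster$dwFA[i]
      roster$dwFC[i] <- roster$dwFB[i] + runif(1, -0.5, 0.5)
    } else if (cls[i] == "mre1_helix") {
      roster$dwFB[i] <- sgn(1) * runif(1, 1, 5)
      roster$dwFC[i] <- roster$dwFB[i] + runif(1, -0.5, 0.5)
    } else if (cls[i] == "mre2") {
      roster$dwFC[i] <- sgn(1) * runif(1, 1, 6)
      roster$dwFB[i] <- runif(1, 0.2, 0.8) * roster$dwFC[i]
    } else {
      roster$dwFB[i] <- runif(1, -0.05, 0.05)
      roster$dwFC[i] <- runif(1, -0.05, 0.05)
    }
  }
  new("GroundTruthScenario", scheme = scheme, composition = composition,
      roster = roster, sigma = sigma, experiments = experiments,
      seed = as.integer(seed))
}

setMethod("show", "GroundTruthScenario", function(object) {
  cat(sprintf("Ground-truth scenario (seed %d): %d residues (%s), sigma = %.3g, %d experiments\n",
              object@seed, nrow(object@roster),
              paste(sprintf("%d %s", table(object@roster$class),
                            names(table(object@roster$class))), collapse = ", "),
              object@sigma, length(object@experiments)))
  invisible(NULL)
})

#' Generate a synthetic CEST dataset from a scenario
#'
#' Forward-simulates every (residue, experiment) profile with the scenario's
#' true scheme and populations, then adds homoscedastic Gaussian intensity
#' noise of the scenario's sigma. Identical seeds give identical datasets.
#'
#' @param scenario a \linkS4class{GroundTruthScenario}
#' @return list with elements \code{dataset} (a \linkS4class{CestDataset})
#'   and \code{truth} (the scenario)
#' @export
generateCestDataset <- function(scenario) {
  set.seed(scenario@seed + 1L)
  sch <- scenario@scheme
  comp <- scenario@composition
  profiles <- list()
  for (i in seq_len(nrow(scenario@roster))) {
    row <- scenario@roster[i, ]
    # in the anchored intermediate only motif residues are folded (relax like
    # B); everything else is still disordered there (relaxes like free)
    spin <- new("ResidueSpinSystem", residueId = as.integer(row$residueId),
                shiftF = row$shiftF, dwFA = row$dwFA, dwFB = row$dwFB,
                dwFC = row$dwFC, R1F = row$R1F, R2F = row$R2F,
                R2A = if (row$class == "crib") row$R2B else row$R2F,
                R2B = row$R2B, R2C = row$R2C, ties = character())
    for (expt in scenario@experiments) {
      p <- simulateProfile(spin, sch, comp, expt, sigma = scenario@sigma)
      if (scenario@sigma > 0)
        p@intensities <- p@intensities +
          rnorm(length(p@offsets), 0, scenario@sigma)
      profiles[[length(profiles) + 1]] <- p
    }
  }
  info <- data.frame(residueId = scenario@roster$residueId,
                     class = scenario@roster$class,
                     assignable = TRUE, excluded = FALSE)
  list(dataset = CestDataset(profiles, comp, info), truth = scenario)
}

#' Generate synthetic relaxation decays
#'
#' @param rates named (by residue id) true decay rates (s-1)
#' @param schedule delay schedule (s); defaults to
#'   \code{\link{defaultDelaySchedule}}
#' @param sigma Gaussian noise standard deviation in intensity units
#' @param I0 common zero-delay amplitude
#' @param seed RNG seed
#' @return list of \linkS4class{DecayCurve}
#' @export
generateDecays <- function(rates, schedule = defaultDelaySchedule(),
                           sigma = 0, I0 = 100, seed = 1) {
  stopifnot(all(rates > 0))
  set.seed(seed)
  ids <- if (is.null(names(rates))) seq_along(rates) else as.integer(names(rates))
  lapply(seq_along(rates), function(i) {
    y <- I0 * exp(-rates[i] * schedule)
    if (sigma > 0) y <- y + rnorm(length(schedule), 0, sigma)
    DecayCurve(ids[i], schedule, y, planeNoise = sigma)
  })
}

#' Thermodynamic ground truth propagated across temperature
#'
#' From an anchor (Kd and dH at a reference temperature, plus a constant
#' dCp), propagates dH(T) = dH_ref + dCp (T - T_ref) and
#' dS(T) = dS_ref + dCp ln(T/T_ref), hence dG(T) and Kd(T).
#'
#' @param T temperatures (K)
#' @param KdRef anchor dissociation constant (uM) at TRef
#' @param dHRef anchor enthalpy (kJ/mol) at TRef
#' @param dCp heat-capacity change (kJ mol-1 K-1)
#' @param TRef reference temperature (K)
#' @return data.frame(T_K, Kd_uM, dG_kJ, dH_kJ, dS_J)
#' @export
propagateThermo <- function(T, KdRef, dHRef, dCp, TRef = 298.15) {
  dGRef <- gibbs(KdRef, TRef)
  dSRef <- (dHRef - dGRef) / TRef * 1000          # J/mol/K
  dH <- dHRef + dCp * (T - TRef)
  dS <- dSRef + dCp * 1000 * log(T / TRef)
  dG <- dH - T * dS / 1000
  data.frame(T_K = T, Kd_uM = exp(dG * 1000 / (GAS_CONSTANT * T)) * 1e6,
             dG_kJ = dG, dH_kJ = dH, dS_J = dS)
}

#' Generate synthetic ITC titration series across temperatures
#'
#' Builds concatenated injection series (default: 3 x 13 injections of 3 uL,
#' 1000 uM titrant into a 125 uM cell) at each temperature from a
#' thermodynamic anchor, via the one-set-of-sites heat model, with optional
#' Gaussian heat noise and duplicate experiments.
#'
#' @param temperatures experiment temperatures (K); default 5, 10, 15 and
#'   35 degrees C
#' @param KdRef,dHRef,dCp,TRef thermodynamic anchor, see
#'   \code{\link{propagateThermo}}
#' @param n true stoichiometry
#' @param cellConc,syringeConc,cellVolume titration design (uM, uM, uL)
#' @param nSegments,injPerSegment,injVolume injection schedule
#' @param sigmaQ Gaussian heat noise (uJ)
#' @param duplicates independent noisy series per temperature
#' @param seed RNG seed
#' @return list with \code{series} (list of \linkS4class{InjectionSeries})
#'   and \code{truth} (the propagated thermodynamic table)
#' @export
generateTitrations <- function(temperatures = c(5, 10, 15, 35) + 273.15,
                               KdRef = 24, dHRef = 0, dCp = -2.8,
                               TRef = 298.15, n = 1,
                               cellConc = 125, syringeConc = 1000,
                               cellVolume = 200, nSegments = 3,
                               injPerSegment = 13, injVolume = 3,
                               sigmaQ = 0, duplicates = 1, seed = 1) {
  set.seed(seed)
  truth <- propagateThermo(temperatures, KdRef, dHRef, dCp, TRef)
  nInj <- nSegments * injPerSegment
  series <- list()
  for (i in seq_along(temperatures)) {
    for (d in seq_len(duplicates)) {
      s <- InjectionSeries(temperature = temperatures[i],
                           cellVolume = cellVolume, cellConc = cellConc,
                           syringeConc = syringeConc,
                           volumes = rep(injVolume, nInj),
                           heats = numeric(nInj),
                           segments = rep(seq_len(nSegments), each = injPerSegment))
      q <- oneSiteHeats(c(n = n, Kd = truth$Kd_uM[i], dH = truth$dH_kJ[i],
                          qOffset = 0), s)
      if (sigmaQ > 0) q <- q + rnorm(nInj, 0, sigmaQ)
      s@heats <- q
      series[[length(series) + 1]] <- s
    }
  }
  list(series = series, truth = truth)
}
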