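#' @import methods
#' @importFrom stats lm coef pf sd quantile rnorm runif median setNames optimize
#' @importFrom utils read.table write.table head tail
#' @useDynLib cestfold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# -- kinetics ----------------------------------------------------------------

#' Linear N-site exchange scheme
#'
#' Houses the microscopic rate constants of a strictly linear binding/folding
#' chain: a bimolecular first step (free IDP + partner, governed by
#' \code{kon}/\code{koff}) followed by first-order conformational steps
#' (\code{kFwd}/\code{kRev}, one pair per subsequent transition). A 4-site
#' scheme has states F, A, B, C (two on-pathway intermediates); the 3-site
#' scheme drops the A state entirely (states F, B, C) rather than zeroing its
#' rates, which would make downstream generators singular.
#'
#' @slot stateLabels ordered state labels, first is the free state
#' @slot kon bimolecular association rate of the first step (M-1 s-1)
#' @slot koff dissociation rate of the first step (s-1)
#' @slot kFwd named forward rates of the subsequent steps (s-1)
#' @slot kRev named reverse rates of the subsequent steps (s-1)
#' @export
setClass("ExchangeScheme",
  representation(stateLabels = "character", kon = "numeric", koff = "numeric",
                 kFwd = "numeric", kRev = "numeric"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@stateLabels)
    if (n < 2L) msg <- c(msg, "need at least two states")
    rates <- c(object@kon, object@koff, object@kFwd, object@kRev)
    if (any(!is.finite(rates)) || any(rates < 0))
      msg <- c(msg, "all rates must be finite and >= 0")
    if (length(object@kFwd) != n - 2L || length(object@kRev) != n - 2L)
      msg <- c(msg, "need one forward/reverse rate pair per subsequent step")
    if (is.null(msg)) TRUE else msg
  })

#' Sample composition and overall binding constraint
#'
#' Total concentrations of the disordered protein (P0) and its folded partner
#' (R0) together with the overall complex dissociation constant; fixes the
#' bound-state population sum used as a constraint in all CEST fits.
#'
#' @slot P0 total IDP concentration (uM)
#' @slot R0 total partner concentration (uM)
#' @slot Kd overall complex dissociation constant (uM)
#' @slot temperature sample temperature (K)
#' @export
setClass("MixtureComposition",
  representation(P0 = "numeric", R0 = "numeric", Kd = "numeric",
                 temperature = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@P0 < 0 || object@R0 < 0) msg <- c(msg, "concentrations must be >= 0")
    if (!is.finite(object@Kd) || object@Kd <= 0) msg <- c(msg, "Kd must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Fractional state populations
#'
#' @slot p named fractional populations, ordered as the scheme's states
#' @export
setClass("StatePopulations",
  representation(p = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@p < -1e-12) || any(object@p > 1 + 1e-12))
      msg <- c(msg, "populations must lie in [0, 1]")
    if (abs(sum(object@p) - 1) > 1e-10)
      msg <- c(msg, "populations must sum to 1 (tol 1e-10)")
    if (is.null(msg)) TRUE else msg
  })

# -- CEST --------------------------------------------------------------------

#' CEST experiment geometry
#'
#' @slot B1 saturation field amplitude (Hz)
#' @slot Tsat saturation period (s)
#' @slot irradiation "cw" or "dante"
#' @slot danteWindow inter-pulse spectral window (Hz, DANTE only; NA for cw)
#' @slot larmor15N 15N Larmor frequency (MHz)
#' @slot carrier irradiation carrier position (ppm)
#' @slot offsets irradiation frequencies (Hz relative to carrier)
#' @export
setClass("CestExperiment",
  representation(B1 = "numeric", Tsat = "numeric", irradiation = "character",
                 danteWindow = "numeric", larmor15N = "numeric",
                 carrier = "numeric", offsets = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@B1 <= 0) msg <- c(msg, "B1 must be > 0")
    if (object@Tsat < 0) msg <- c(msg, "Tsat must be >= 0")
    if (!object@irradiation %in% c("cw", "dante"))
      msg <- c(msg, "irradiation must be 'cw' or 'dante'")
    if (object@irradiation == "dante" &&
        (!is.finite(object@danteWindow) || object@danteWindow <= 2 * object@B1))
      msg <- c(msg, "DANTE requires danteWindow > 2*B1")
    if (is.unsorted(object@offsets, strictly = TRUE))
      msg <- c(msg, "offsets must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  })

#' Per-residue spin system
#'
#' Chemical shift of the free state, shift differences of the bound states
#' relative to free, and relaxation rates. dwAB and dwBC are exact identities
#' of the stored dwFA/dwFB/dwFC (see \code{\link{dwAB}}).
#'
#' @slot residueId sequence position
#' @slot shiftF major-state (free) chemical shift (ppm)
#' @slot dwFA,dwFB,dwFC shift differences of states A/B/C from F (ppm);
#'   dwFA is NA for a 3-site spin system
#' @slot R1F longitudinal relaxation rate shared by all states (s-1)
#' @slot R2F,R2A,R2B,R2C per-state transverse relaxation rates (s-1)
#' @slot ties character record of the tying rules applied ("R2A=R2F",
#'   "R2A=R2B", "R2B=R2C")
#' @export
setClass("ResidueSpinSystem",
  representation(residueId = "integer", shiftF = "numeric",
                 dwFA = "numeric", dwFB = "numeric", dwFC = "numeric",
                 R1F = "numeric", R2F = "numeric", R2A = "numeric",
                 R2B = "numeric", R2C = "numeric", ties = "character"),
  validity = function(object) {
    r <- c(object@R1F, object@R2F, object@R2B, object@R2C)
    if (any(!is.finite(r)) || any(r <= 0)) "relaxation rates must be > 0" else TRUE
  })

#' One saturation profile
#'
#' @slot residueId residue
#' @slot experiment the \linkS4class{CestExperiment} geometry
#' @slot offsets irradiation offsets (Hz relative to carrier)
#' @slot intensities normalized intensities I/I0
#' @slot sigmas per-point uncertainty
#' @slot mask per-point inclusion flag (FALSE = excluded from fitting)
#' @export
setClass("CestProfile",
  representation(residueId = "integer", experiment = "CestExperiment",
                 offsets = "numeric", intensities = "numeric",
                 sigmas = "numeric", mask = "logical"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@offsets)
    if (n > 1 && is.unsorted(object@offsets, strictly = TRUE))
      msg <- c(msg, "offsets must be strictly increasing")
    if (any(!is.finite(object@intensities))) msg <- c(msg, "intensities must be finite")
    if (length(object@intensities) != n || length(object@mask) != n ||
        length(object@sigmas) != n)
      msg <- c(msg, "offsets, intensities, sigmas and mask must have equal length")
    if (is.null(msg)) TRUE else msg
  })

#' A full CEST dataset: profiles across residues and B1 fields
#'
#' @slot profiles list of \linkS4class{CestProfile}
#' @slot composition the \linkS4class{MixtureComposition} carrying the Kd
#'   constraint
#' @slot residueInfo data.frame with columns residueId, class, assignable,
#'   excluded
#' @export
setClass("CestDataset",
  representation(profiles = "list", composition = "MixtureComposition",
                 residueInfo = "data.frame"),
  validity = function(object) {
    keys <- vapply(object@profiles, function(p)
      paste(p@residueId, p@experiment@B1, p@experiment@irradiation), "")
    if (anyDuplicated(keys)) "duplicate (residue, B1) profile" else TRUE
  })

#' Specification of a residue-specific or global CEST fit
#'
#' @slot model "3site" or "4site"
#' @slot globalInit named initial values of the global parameters
#'   (4-site: koff, kexAB, kexBC, KeqAB, KeqBC; 3-site: koff, kBC, kCB)
#' @slot residueInit data.frame of residue-specific initial values
#'   (residueId, dwFA, dwFB, dwFC, R1F, R2F, R2B, R2C)
#' @slot cribSet residues whose R2A is tied to R2B (inside the anchoring
#'   motif); all others use R2A = R2F
#' @slot tieR2BC residues with the optional R2B = R2C tie
#' @slot rateBounds lower/upper bound on all rate-like parameters (s-1)
#' @slot dwBound symmetric bound on shift differences (ppm)
#' @slot fitShiftF refine the major-state position within +/- 0.3 ppm of its
#'   initial estimate (needed when shiftF comes from profile minima rather
#'   than from assigned peak positions)
#' @export
setClass("FitSpec",
  representation(model = "character", globalInit = "numeric",
                 residueInit = "data.frame", cribSet = "integer",
                 tieR2BC = "integer", rateBounds = "numeric",
                 dwBound = "numeric", fitShiftF = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!object@model %in% c("3site", "4site")) msg <- c(msg, "model must be 3site or 4site")
    if (length(object@rateBounds) != 2 || any(object@rateBounds <= 0))
      msg <- c(msg, "rateBounds must be two positive values")
    if (is.null(msg)) TRUE else msg
  })

#' Result of a (global or residue-specific) least-squares CEST fit
#'
#' @slot model "3site" or "4site"
#' @slot globalPar named best-fit global parameters
#' @slot globalSE covariance-derived uncertainties (NA when the covariance is
#'   singular)
#' @slot residuePar data.frame of residue-specific best-fit values
#' @slot chisq total masked chi-square
#' @slot nPoints number of contributing (masked-in) data points
#' @slot nPar number of free parameters
#' @slot residuals list of per-profile weighted residual vectors
#' @slot converged optimizer convergence flag
#' @slot composition the composition used for the population constraint
#' @export
setClass("GlobalFitResult",
  representation(model = "character", globalPar = "numeric", globalSE = "numeric",
                 residuePar = "data.frame", chisq = "numeric",
                 nPoints = "integer", nPar = "integer", residuals = "list",
                 converged = "logical", composition = "MixtureComposition"),
  validity = function(object) {
    msg <- NULL
    if (is.finite(object@chisq) && object@chisq < 0) msg <- c(msg, "chisq must be >= 0")
    if (object@nPoints - object@nPar <= 0) msg <- c(msg, "dof must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Bootstrap uncertainty summary for global parameters
#'
#' @slot nReplicates number of requested replicates
#' @slot replicates matrix of replicate estimates (rows = replicates)
#' @slot ci68 2 x p matrix of 16/84 percentile bounds
#' @slot pointEstimate the point fit the replicates were started from
#' @slot nDropped replicates dropped for non-convergence
#' @slot seed RNG seed used
#' @export
setClass("BootstrapSummary",
  representation(nReplicates = "integer", replicates = "matrix", ci68 = "matrix",
                 pointEstimate = "numeric", nDropped = "integer", seed = "integer"))

# -- relaxation --------------------------------------------------------------

#' A relaxation decay curve
#'
#' @slot residueId residue
#' @slot delays relaxation delays (s); duplicates allowed
#' @slot intensities signal intensities (arbitrary units)
#' @slot planeNoise per-delay intensity standard deviation
#' @export
setClass("DecayCurve",
  representation(residueId = "integer", delays = "numeric",
                 intensities = "numeric", planeNoise = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(unique(object@delays)) < 3) msg <- c(msg, "need >= 3 distinct delays")
    if (any(!is.finite(object@intensities))) msg <- c(msg, "intensities must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Fitted relaxation rate with Monte Carlo uncertainty
#'
#' @slot rate fitted decay rate (s-1)
#' @slot amplitude fitted zero-delay amplitude
#' @slot rateSD Monte Carlo standard deviation of the rate (s-1)
#' @slot nMonteCarlo number of Monte Carlo draws (0 for point fits)
#' @slot seed RNG seed of the Monte Carlo stage
#' @slot flagged TRUE for non-decaying or non-converged fits
#' @export
setClass("RateResult",
  representation(residueId = "integer", rate = "numeric", amplitude = "numeric",
                 rateSD = "numeric", nMonteCarlo = "integer", seed = "integer",
                 flagged = "logical"))

# -- ITC ---------------------------------------------------------------------

#' An ITC injection series (possibly concatenated across syringe refills)
#'
#' @slot temperature experiment temperature (K)
#' @slot cellVolume calorimeter cell volume (uL)
#' @slot cellConc initial cell (macromolecule) concentration (uM)
#' @slot syringeConc syringe (titrant) concentration (uM)
#' @slot volumes per-injection volumes (uL)
#' @slot heats per-injection integrated heats (uJ)
#' @slot segments integer segment id per injection (refill boundaries)
#' @export
setClass("InjectionSeries",
  representation(temperature = "numeric", cellVolume = "numeric",
                 cellConc = "numeric", syringeConc = "numeric",
                 volumes = "numeric", heats = "numeric", segments = "integer"),
  validity = function(object) {
    msg <- NULL
    if (any(object@volumes <= 0)) msg <- c(msg, "injection volumes must be > 0")
    if (object@cellConc <= 0 || object@syringeConc <= 0 || object@cellVolume <= 0)
      msg <- c(msg, "volumes and concentrations must be > 0")
    if (any(!is.finite(object@heats))) msg <- c(msg, "heats must be finite")
    if (length(object@heats) != length(object@volumes) ||
        length(object@segments) != length(object@volumes))
      msg <- c(msg, "volumes, heats and segments must have equal length")
    if (is.null(msg)) TRUE else msg
  })

#' One-set-of-sites fit of an injection series
#'
#' @slot n stoichiometry
#' @slot Kd dissociation constant (uM)
#' @slot dH binding enthalpy (kJ/mol)
#' @slot qOffset per-injection background heat (uJ)
#' @slot se named parameter uncertainties
#' @slot converged,flagged fit status
#' @export
setClass("OneSiteFit",
  representation(n = "numeric", Kd = "numeric", dH = "numeric",
                 qOffset = "numeric", se = "numeric", converged = "logical",
                 flagged = "logical"),
  validity = function(object) {
    if (object@Kd <= 0 || object@n <= 0) "Kd and n must be > 0" else TRUE
  })

#' Per-temperature binding thermodynamics
#'
#' Rows hold (T, Kd, dG, dH, dS, TdS) with dG = dH - T*dS and
#' dG = R*T*ln(Kd / 1 M) holding identically per row.
#'
#' @slot table data.frame with columns T_K, Kd_uM, dG_kJ, dH_kJ, dS_J, TdS_kJ
#' @export
setClass("ThermoTable",
  representation(table = "data.frame"),
  validity = function(object) {
    need <- c("T_K", "Kd_uM", "dG_kJ", "dH_kJ", "dS_J", "TdS_kJ")
    if (!all(need %in% names(object@table)))
      return(paste("table needs columns:", paste(need, collapse = ", ")))
    ok <- abs(object@table$dG_kJ -
              (object@table$dH_kJ - object@table$T_K * object@table$dS_J / 1000)) < 1e-9
    if (!all(ok)) "dG = dH - T*dS violated" else TRUE
  })

#' Spolar-Record entropy decomposition
#'
#' Partition of the total binding entropy at temperature T into
#' conformational, desolvation and rotational/translational terms, with the
#' folded-residue estimate derived from the conformational component.
#' All entropies in J mol-1 K-1.
#'
#' @slot T evaluation temperature (K)
#' @slot dSTotal,dSConf,dSDesolv,dSrt entropy components (J mol-1 K-1)
#' @slot TS iso-entropic temperature (K)
#' @slot dCp heat-capacity change (kJ mol-1 K-1)
#' @slot perResidue assumed per-residue conformational entropy loss (J mol-1 K-1)
#' @slot foldedResidues estimated number of residues folding upon binding
#' @export
setClass("EntropyDecomposition",
  representation(T = "numeric", dSTotal = "numeric", dSConf = "numeric",
                 dSDesolv = "numeric", dSrt = "numeric", TS = "numeric",
                 dCp = "numeric", perResidue = "numeric",
                 foldedResidues = "numeric"))

# -- synthetic ---------------------------------------------------------------

#' Ground-truth scenario for synthetic-data generation
#'
#' @slot scheme true \linkS4class{ExchangeScheme}
#' @slot composition true \linkS4class{MixtureComposition}
#' @slot roster data.frame of residues: residueId, class, shiftF, dwFA, dwFB,
#'   dwFC, R1F, R2F, R2B, R2C
#' @slot sigma intensity noise (fraction of the reference intensity)
#' @slot experiments list of \linkS4class{CestExperiment}
#' @slot seed RNG seed the scenario was drawn with
#' @export
setClass("GroundTruthScenario",
  representation(scheme = "ExchangeScheme", composition = "MixtureComposition",
                 roster = "data.frame", sigma = "numeric", experiments = "list",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@roster) == 0) msg <- c(msg, "roster must be non-empty")
    if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
    if (anyDuplicated(object@roster$residueId)) msg <- c(msg, "duplicate residues")
    if (is.null(msg)) TRUE else msg
  })
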