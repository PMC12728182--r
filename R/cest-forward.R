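# Forward simulation of 15N CEST profiles for an exchanging spin under
# continuous-wave or DANTE (D-CEST) saturation, by propagating the
# Bloch-McConnell equations in a basis of 3 Cartesian components per state.
# Offsets are stored in Hz relative to the carrier; ppm <-> Hz conversion uses
# the configured 15N Larmor frequency (ppm increasing downfield), in one place
# only (ppmToHz/hzToPpm).

#' Construct a CEST experiment
#'
#' @param B1 saturation field amplitude (Hz)
#' @param Tsat saturation period (s)
#' @param irradiation "cw" (single-frequency continuous wave) or "dante"
#'   (multi-frequency pulse train, D-CEST)
#' @param danteWindow inter-pulse spectral window (Hz; required for DANTE)
#' @param larmor15N 15N Larmor frequency (MHz), e.g. 96.3 at a 950 MHz 1H field
#' @param carrier irradiation carrier position (ppm)
#' @param offsets irradiation frequencies (Hz relative to carrier)
#' @return a \linkS4class{CestExperiment}
#' @export
CestExperiment <- function(B1, Tsat, irradiation = c("cw", "dante"),
                           danteWindow = NA_real_, larmor15N = 96.3,
                           carrier = 118.5, offsets) {
  irradiation <- match.arg(irradiation)
  new("CestExperiment", B1 = B1, Tsat = Tsat, irradiation = irradiation,
      danteWindow = danteWindow, larmor15N = larmor15N, carrier = carrier,
      offsets = as.numeric(offsets))
}

setMethod("show", "CestExperiment", function(object) {
  cat(sprintf("CEST experiment: B1 = %.3g Hz (%s%s), Tsat = %.3g s, %d offsets\n",
              object@B1, object@irradiation,
              if (object@irradiation == "dante")
                sprintf(", window %.0f Hz", object@danteWindow) else "",
              object@Tsat, length(object@offsets)))
  invisible(NULL)
})

#' Construct a residue spin system
#'
#' @param residueId sequence position
#' @param shiftF free-state chemical shift (ppm)
#' @param dwFA,dwFB,dwFC shift differences of the bound states from F (ppm);
#'   leave dwFA as NA for a 3-site system
#' @param R1F longitudinal relaxation rate (s-1), shared by all states
#' @param R2F,R2B,R2C transverse relaxation rates (s-1)
#' @param R2A transverse rate of the anchored intermediate; defaults to R2F
#'   (the tie used outside the anchoring motif)
#' @param ties character record of applied tying rules
#' @return a \linkS4class{ResidueSpinSystem}
#' @export
ResidueSpinSystem <- function(residueId, shiftF, dwFA = NA_real_, dwFB, dwFC,
                              R1F, R2F, R2B, R2C = R2B, R2A = R2F,
                              ties = character()) {
  new("ResidueSpinSystem", residueId = as.integer(residueId), shiftF = shiftF,
      dwFA = as.numeric(dwFA), dwFB = dwFB, dwFC = dwFC, R1F = R1F, R2F = R2F,
      R2A = R2A, R2B = R2B, R2C = R2C, ties = ties)
}

#' Shift difference between successive states
#'
#' Exact identities of the stored free-state-referenced differences:
#' dwAB = dwFB - dwFA, dwBC = dwFC - dwFB.
#' @param spin a \linkS4class{ResidueSpinSystem}
#' @export
dwAB <- function(spin) spin@dwFB - spin@dwFA

#' @rdname dwAB
#' @export
dwBC <- function(spin) spin@dwFC - spin@dwFB

#' Convert ppm to Hz (and back) at the experiment's Larmor frequency
#'
#' @param ppm,hz value to convert
#' @param expt a \linkS4class{CestExperiment}
#' @return frequency in Hz relative to the carrier, or ppm
#' @export
ppmToHz <- function(ppm, expt) (ppm - expt@carrier) * expt@larmor15N

#' @rdname ppmToHz
#' @export
hzToPpm <- function(hz, expt) hz / expt@larmor15N + expt@carrier

# Per-state resonance positions (Hz relative to carrier) for a spin system
# under a given scheme ordering.
stateShiftsHz <- function(spin, scheme, expt) {
  labs <- stateLabels(scheme)
  dw <- c(F = 0, A = spin@dwFA, B = spin@dwFB, C = spin@dwFC)[labs]
  if (any(is.na(dw)))
    stop("spin system lacks shift differences for states: ",
         paste(labs[is.na(dw)], collapse = ", "))
  ppmToHz(spin@shiftF + unname(dw), expt)
}

stateR2 <- function(spin, scheme) {
  labs <- stateLabels(scheme)
  unname(c(F = spin@R2F, A = spin@R2A, B = spin@R2B, C = spin@R2C)[labs])
}

# Exchange generator consistent with a fixed population vector: first step
# uses detailed balance (k_FA = koff * p_first_bound / p_F), subsequent steps
# use the stored rates.
rateMatrixFromPops <- function(scheme, pops) {
  p <- populations(pops)
  n <- nStates(scheme)
  if (length(p) != n) stop("population/scheme dimension mismatch")
  if (p[[1]] <= 0) stop("p_F = 0: first-step rate undefined")
  fwd <- c(scheme@koff * p[[2]] / p[[1]], unname(scheme@kFwd))
  rev <- c(scheme@koff, unname(scheme@kRev))
  K <- matrix(0, n, n, dimnames = list(stateLabels(scheme), stateLabels(scheme)))
  for (i in seq_len(n - 1)) {
    K[i + 1, i] <- fwd[i]
    K[i, i + 1] <- rev[i]
  }
  diag(K) <- -colSums(K)
  K
}

#' Bloch-McConnell evolution matrix
#'
#' Assembles the 3N x 3N generator over the (state x \{x, y, z\}) basis for a
#' single irradiation offset: diagonal blocks carry relaxation (-R2 on x/y,
#' -R1 on z), precession at Omega_i = 2 pi (shift_i - carrier - offset) and
#' nutation at omega_1 = 2 pi B1 about x; off-diagonal blocks carry the
#' first-order exchange rates, columns of the exchange part summing to zero
#' per Cartesian component.
#'
#' @param spin a \linkS4class{ResidueSpinSystem}
#' @param scheme an \linkS4class{ExchangeScheme}
#' @param pops a \linkS4class{StatePopulations} consistent with the scheme
#' @param expt a \linkS4class{CestExperiment}
#' @param offset irradiation offset (Hz relative to carrier)
#' @param B1 saturation amplitude (Hz); defaults to the experiment's B1 (use
#'   0 for free precession)
#' @return the 3N x 3N evolution matrix (rad/s units on precession terms)
#' @export
bmGenerator <- function(spin, scheme, pops, expt, offset, B1 = expt@B1) {
  omega <- 2 * pi * (stateShiftsHz(spin, scheme, expt) - offset)
  K <- rateMatrixFromPops(scheme, pops)
  .bmGeneratorC(omega, 2 * pi * B1, spin@R1F, stateR2(spin, scheme), K)
}

#' Propagate magnetization under continuous-wave saturation
#'
#' @param generator a 3N x 3N evolution matrix from \code{\link{bmGenerator}}
#' @param M0 initial magnetization vector (length 3N)
#' @param Tsat saturation period (s)
#' @return the magnetization vector expm(generator * Tsat) \%*\% M0
#' @export
propagateCW <- function(generator, M0, Tsat) {
  if (Tsat < 0) stop("Tsat must be >= 0")
  if (length(M0) != nrow(generator)) stop("M0/generator dimension mismatch")
  if (Tsat == 0) return(M0)
  drop(.propagateC(generator, M0, Tsat))
}

#' Propagate magnetization under a DANTE pulse train
#'
#' Models D-CEST saturation as ideal instantaneous rotations of flip angle
#' 2 pi B1 / window about the B1 axis, separated by free-precession periods of
#' 1/window; the per-period propagator is applied round(Tsat * window) times.
#' The resulting saturation profile is periodic in the offset with period
#' equal to the DANTE window (frequency comb aliasing).
#'
#' @inheritParams bmGenerator
#' @param M0 initial magnetization (defaults to z-magnetization proportional
#'   to the state populations)
#' @return the magnetization vector after Tsat
#' @export
propagateDante <- function(spin, scheme, pops, expt, offset, M0 = NULL) {
  if (expt@irradiation != "dante") stop("experiment is not DANTE")
  w <- expt@danteWindow
  n <- length(stateLabels(scheme))
  if (is.null(M0)) {
    M0 <- numeric(3 * n)
    M0[3 * seq_len(n) - 0] <- populations(pops)  # z components
  }
  nper <- round(expt@Tsat * w)
  if (expt@Tsat == 0 || nper == 0) {
    if (expt@Tsat > 0) {
      warning("Tsat * danteWindow < 1: falling back to CW propagation")
      G <- bmGenerator(spin, scheme, pops, expt, offset)
      return(propagateCW(G, M0, expt@Tsat))
    }
    return(M0)
  }
  G0 <- bmGenerator(spin, scheme, pops, expt, offset, B1 = 0)
  U0 <- .propagateC(G0, diag(3 * n), 1 / w)  # expm(G0 / w) acting on identity
  theta <- 2 * pi * expt@B1 / w
  rot <- matrix(c(1, 0, 0, 0, cos(theta), sin(theta), 0, -sin(theta), cos(theta)), 3, 3)
  P <- kronecker(diag(n), rot)
  U <- P %*% U0
  M <- M0
  for (i in seq_len(nper)) M <- U %*% M
  drop(M)
}

#' Simulate a CEST profile
#'
#' Initial magnetization is z-only, proportional to the state populations
#' (fixed by the composition's bound fraction and the scheme's per-step
#' equilibrium constants). The observable is the summed z-magnetization after
#' Tsat, normalized by a zero-length-saturation reference.
#'
#' @param spin a \linkS4class{ResidueSpinSystem}
#' @param scheme an \linkS4class{ExchangeScheme}
#' @param comp a \linkS4class{MixtureComposition}
#' @param expt a \linkS4class{CestExperiment}
#' @param sigma per-point uncertainty recorded in the profile (no noise is
#'   added here; see \code{\link{generateCestDataset}})
#' @return a \linkS4class{CestProfile}
#' @export
simulateProfile <- function(spin, scheme, comp, expt, sigma = 0) {
  if (length(expt@offsets) == 0) stop("experiment has no offsets")
  pops <- partitionPopulations(boundFraction(comp), scheme)
  intens <- simulateIntensities(spin, scheme, pops, expt)
  new("CestProfile", residueId = spin@residueId, experiment = expt,
      offsets = expt@offsets, intensities = intens,
      sigmas = rep(sigma, length(expt@offsets)),
      mask = rep(TRUE, length(expt@offsets)))
}

# Intensity vector at the experiment's offsets for fixed populations; the
# hot path used by both simulation and fitting (C++ backend).
simulateIntensities <- function(spin, scheme, pops, expt) {
  K <- rateMatrixFromPops(scheme, pops)
  drop(.cestProfileC(expt@offsets, stateShiftsHz(spin, scheme, expt),
                     populations(pops), K, spin@R1F, stateR2(spin, scheme),
                     expt@B1, expt@Tsat,
                     expt@irradiation == "dante",
                     if (is.na(expt@danteWindow)) 0 else expt@danteWindow))
}

#' Exclusion mask around the major-state resonance
#'
#' Marks points within +/- B1 (in Hz) of the major-state frequency for
#' exclusion from fitting: that window is dominated by on-resonance
#' saturation and most sensitive to B1 inhomogeneity, while carrying little
#' exchange information. For DANTE profiles the distance is computed modulo
#' the window (the resonance position aliases into the principal band).
#'
#' @param profile a \linkS4class{CestProfile}
#' @param B1 exclusion half-width (Hz); defaults to the profile's B1
#' @param majorShift major-state shift (ppm); defaults to the offset of the
#'   profile minimum
#' @return logical mask, TRUE = keep, FALSE = excluded
#' @export
exclusionMask <- function(profile, B1 = profile@experiment@B1,
                          majorShift = NULL) {
  off <- profile@offsets
  if (length(off) == 0) return(logical(0))
  expt <- profile@experiment
  pos <- if (is.null(majorShift)) off[which.min(profile@intensities)]
         else ppmToHz(majorShift, expt)
  d <- off - pos
  if (expt@irradiation == "dante" && is.finite(expt@danteWindow)) {
    w <- expt@danteWindow
    d <- (d + w / 2) %% w - w / 2
  }
  abs(d) > B1
}

setMethod("show", "CestProfile", function(object) {
  cat(sprintf("CEST profile: residue %d, B1 = %.3g Hz (%s), %d points (%d masked out)\n",
              object@residueId, object@experiment@B1,
              object@experiment@irradiation, length(object@offsets),
              sum(!object@mask)))
  invisible(NULL)
})

setMethod("show", "CestDataset", function(object) {
  b1 <- sort(unique(vapply(object@profiles, function(p) p@experiment@B1, 0)))
  cat(sprintf("CEST dataset: %d profiles, %d residues, B1 fields: %s Hz\n",
              length(object@profiles), nrow(object@residueInfo),
              paste(signif(b1, 3), collapse = ", ")))
  show(object@composition)
  invisible(NULL)
})
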