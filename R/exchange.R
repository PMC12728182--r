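# Linear N-site exchange kinetics: population algebra under the binding
# constraint and closed-form relations between microscopic rates and the
# macroscopic dissociation constant. Concentrations are in uM throughout;
# conversion to M happens only where a bimolecular rate enters.

#' Construct a linear exchange scheme
#'
#' The 4-site model describes hierarchical folding-upon-binding of an IDP
#' region: the free state F binds its partner to form an anchored intermediate
#' A, which folds through a second intermediate B into the final complex C
#' (F <-> A <-> B <-> C, strictly linear). The 3-site model omits the A state
#' (F <-> B <-> C).
#'
#' @param model "4site" (states F, A, B, C) or "3site" (states F, B, C)
#' @param kon bimolecular association rate of the first step (M-1 s-1)
#' @param koff dissociation rate of the first step (s-1)
#' @param kAB,kBA forward/reverse rates of the A -> B folding step (s-1;
#'   4-site only)
#' @param kBC,kCB forward/reverse rates of the B -> C folding step (s-1)
#' @return an \linkS4class{ExchangeScheme}
#' @examples
#' sch <- ExchangeScheme("4site", kon = 7.3e5, koff = 56,
#'                       kAB = 72, kBA = 64, kBC = 89, kCB = 94)
#' keq(sch)
#' apparentKd(sch)
#' @export
ExchangeScheme <- function(model = c("4site", "3site"), kon, koff,
                           kAB = NA_real_, kBA = NA_real_, kBC, kCB) {
  model <- match.arg(model)
  if (model == "4site") {
    new("ExchangeScheme", stateLabels = c("F", "A", "B", "C"),
        kon = kon, koff = koff,
        kFwd = c(AB = kAB, BC = kBC), kRev = c(BA = kBA, CB = kCB))
  } else {
    new("ExchangeScheme", stateLabels = c("F", "B", "C"),
        kon = kon, koff = koff,
        kFwd = c(BC = kBC), kRev = c(CB = kCB))
  }
}

#' @rdname stateLabels
#' @export
setMethod("stateLabels", "ExchangeScheme", function(object) object@stateLabels)

#' @rdname nStates
#' @export
setMethod("nStates", "ExchangeScheme", function(object) length(object@stateLabels))

#' @rdname keq
#' @export
setMethod("keq", "ExchangeScheme", function(object) {
  k <- object@kFwd / object@kRev
  names(k) <- names(object@kFwd)
  k
})

#' @rdname kex
#' @export
setMethod("kex", "ExchangeScheme", function(object) {
  k <- object@kFwd + object@kRev
  names(k) <- names(object@kFwd)
  k
})

setMethod("show", "ExchangeScheme", function(object) {
  cat(sprintf("Linear %d-site exchange scheme: %s\n", nStates(object),
              paste(object@stateLabels, collapse = " <-> ")))
  cat(sprintf("  kon  = %.4g M-1 s-1, koff = %.4g s-1\n", object@kon, object@koff))
  for (s in names(object@kFwd))
    cat(sprintf("  k_%s = %.4g s-1, k_%s = %.4g s-1 (k_ex = %.4g, K_eq = %.4g)\n",
                s, object@kFwd[s], names(object@kRev)[match(s, names(object@kFwd))],
                object@kRev[match(s, names(object@kFwd))],
                kex(object)[s], keq(object)[s]))
  invisible(NULL)
})

#' Construct a mixture composition
#'
#' @param P0 total IDP concentration (uM)
#' @param R0 total partner concentration (uM)
#' @param Kd overall complex dissociation constant (uM)
#' @param temperature temperature (K)
#' @return a \linkS4class{MixtureComposition}
#' @export
MixtureComposition <- function(P0, R0, Kd, temperature = 298.15) {
  if (any(c(P0, R0) < 0)) stop("concentrations must be >= 0")
  new("MixtureComposition", P0 = P0, R0 = R0, Kd = Kd, temperature = temperature)
}

setMethod("show", "MixtureComposition", function(object) {
  cat(sprintf("Mixture: P0 = %.4g uM, R0 = %.4g uM, Kd = %.4g uM, T = %.2f K\n",
              object@P0, object@R0, object@Kd, object@temperature))
  cat(sprintf("  bound fraction of P: %.4f\n", boundFraction(object)))
  invisible(NULL)
})

#' @rdname populations
#' @export
setMethod("populations", "StatePopulations", function(object) object@p)

setMethod("show", "StatePopulations", function(object) {
  cat("State populations:\n")
  print(round(object@p, 6))
  invisible(NULL)
})

#' Fraction of the IDP bound in any complexed state
#'
#' Solves the bimolecular mass-balance quadratic
#' \eqn{C^2 - C(P0 + R0 + Kd) + P0 R0 = 0} for the complex concentration C
#' and returns C/P0. The smaller quadratic root is the physical one
#' (it alone satisfies \eqn{C \le \min(P0, R0)}).
#'
#' @param comp a \linkS4class{MixtureComposition}
#' @return the bound fraction of the IDP (dimensionless, in [0, 1))
#' @examples
#' boundFraction(MixtureComposition(P0 = 500, R0 = 100, Kd = 24))
#' @export
boundFraction <- function(comp) {
  stopifnot(is(comp, "MixtureComposition"))
  P0 <- comp@P0; R0 <- comp@R0; Kd <- comp@Kd
  if (P0 <= 0) stop("P0 must be > 0")
  if (R0 == 0) return(0)
  b <- P0 + R0 + Kd
  disc <- b^2 - 4 * P0 * R0
  if (disc < 0) stop("internal inconsistency: negative discriminant in mass balance")
  # smaller root, written to avoid cancellation
  C <- 2 * P0 * R0 / (b + sqrt(disc))
  C / P0
}

#' Partition the total bound fraction over the bound states
#'
#' Distributes a fixed total bound population over the chain's bound states
#' according to the per-step equilibrium constants:
#' pA = bound/(1 + K_AB + K_AB K_BC), pB = pA K_AB, pC = pB K_BC
#' (two-term analogue for the 3-site scheme). This is the population
#' constraint applied in all CEST fits: the bound sum is fixed by the
#' composition, not fitted.
#'
#' @param totalBound total bound fraction in [0, 1)
#' @param scheme an \linkS4class{ExchangeScheme}
#' @return a \linkS4class{StatePopulations}
#' @export
partitionPopulations <- function(totalBound, scheme) {
  if (!is.finite(totalBound) || totalBound < 0 || totalBound >= 1)
    stop("totalBound must lie in [0, 1)")
  K <- keq(scheme)
  # cumulative products 1, K1, K1*K2, ... over bound states
  w <- cumprod(c(1, K))
  pb <- totalBound * w / sum(w)
  p <- c(1 - totalBound, pb)
  names(p) <- stateLabels(scheme)
  new("StatePopulations", p = p)
}

#' Apparent overall dissociation constant of the linear scheme
#'
#' The macroscopic Kd implied by the microscopic rates:
#' \deqn{K_d = \frac{k_{off}/k_{on}}{1 + K_{AB}(1 + K_{BC})}}
#' (3-site scheme: divide by \eqn{1 + K_{BC}}). Downstream folding steps pull
#' the equilibrium toward the complex, so the apparent Kd is tighter than the
#' first-step Kd1 = koff/kon.
#'
#' @param scheme an \linkS4class{ExchangeScheme}
#' @return apparent Kd in uM
#' @export
apparentKd <- function(scheme) {
  if (scheme@kon <= 0) stop("kon must be > 0 to define a dissociation constant")
  if (any(scheme@kRev <= 0)) stop("zero reverse rate: downstream equilibrium undefined")
  K <- keq(scheme)
  Kd1 <- scheme@koff / scheme@kon * 1e6   # M -> uM
  # 1 + K1 + K1*K2 + ... = sum of cumulative products
  Kd1 / sum(cumprod(c(1, K)))
}

#' Pseudo-first-order association rate under the population constraint
#'
#' The effective F -> (first bound state) rate implied by detailed balance
#' once the populations are fixed: k_on,app = koff * p_first / p_F. Equals
#' kon * [partner_free] (in s-1) when kon and the free-partner concentration
#' are known.
#'
#' @param scheme an \linkS4class{ExchangeScheme}
#' @param comp a \linkS4class{MixtureComposition}
#' @return first-order association rate (s-1)
#' @export
pseudoFirstOrderRate <- function(scheme, comp) {
  fb <- boundFraction(comp)
  pops <- populations(partitionPopulations(fb, scheme))
  pF <- pops[[1]]
  if (pF <= 0) stop("p_F = 0: pseudo-first-order rate undefined")
  scheme@koff * pops[[2]] / pF
}

#' Continuous-time rate generator of the exchange chain
#'
#' N x N matrix with element (i, j) = rate from state j to state i (i != j)
#' and diagonal such that columns sum to zero. The first step uses the
#' pseudo-first-order association rate consistent with the composition's
#' population constraint, so the stationary distribution equals
#' \code{\link{partitionPopulations}}.
#'
#' @param scheme an \linkS4class{ExchangeScheme}
#' @param comp a \linkS4class{MixtureComposition}
#' @return the N x N generator matrix, dimnames = state labels
#' @export
rateMatrix <- function(scheme, comp) {
  n <- nStates(scheme)
  kfa <- pseudoFirstOrderRate(scheme, comp)
  fwd <- c(kfa, unname(scheme@kFwd))   # rates i -> i+1
  rev <- c(scheme@koff, unname(scheme@kRev))  # rates i+1 -> i
  K <- matrix(0, n, n, dimnames = list(stateLabels(scheme), stateLabels(scheme)))
  for (i in seq_len(n - 1)) {
    K[i + 1, i] <- fwd[i]
    K[i, i + 1] <- rev[i]
  }
  diag(K) <- -colSums(K)
  K
}
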