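# Staged inference on CEST datasets: noise estimation, dip picking,
# residue-specific 3-site fits with minor-state assignment, global 3-/4-site
# fits under the binding population constraint, nested-model comparison,
# bootstrap uncertainties, anchoring-motif boundary search and
# profile-likelihood grid searches.
#
# All fits are weighted Levenberg-Marquardt (minpack.lm). Rate-like and
# equilibrium parameters are optimized on a log10 scale (they are positive
# and span decades); shift differences are linear. The bound-state population
# sum is never a fit parameter: it is fixed from the composition at every
# iteration.

#' Construct a CEST dataset
#'
#' @param profiles list of \linkS4class{CestProfile}
#' @param composition \linkS4class{MixtureComposition} carrying the Kd
#'   constraint
#' @param residueInfo data.frame with columns residueId, class, assignable,
#'   excluded; defaults to all-assignable metadata derived from the profiles
#' @return a \linkS4class{CestDataset}
#' @export
CestDataset <- function(profiles, composition, residueInfo = NULL) {
  ids <- sort(unique(vapply(profiles, function(p) p@residueId, 1L)))
  if (is.null(residueInfo))
    residueInfo <- data.frame(residueId = ids, class = "unknown",
                              assignable = TRUE, excluded = FALSE)
  new("CestDataset", profiles = profiles, composition = composition,
      residueInfo = residueInfo)
}

#' Construct a fit specification
#'
#' @param model "3site" or "4site"
#' @param globalInit named initial global parameters: koff, kBC, kCB (3-site)
#'   or koff, kexAB, kexBC, KeqAB, KeqBC (4-site)
#' @param residueInit data.frame with columns residueId, shiftF, dwFA, dwFB,
#'   dwFC, R1F, R2F, R2B, R2C (shiftF is fixed, not optimized)
#' @param cribSet residues inside the anchoring motif (R2A tied to R2B;
#'   others tied to R2F); 4-site only
#' @param tieR2BC residues with the optional R2B = R2C tie
#' @param rateBounds bounds for all rate-like parameters (s-1)
#' @param dwBound symmetric bound for shift differences (ppm)
#' @return a \linkS4class{FitSpec}
#' @export
FitSpec <- function(model, globalInit, residueInit, cribSet = integer(),
                    tieR2BC = integer(), rateBounds = c(1e-3, 1e4),
                    dwBound = 20, fitShiftF = TRUE) {
  need <- if (model == "4site") c("koff", "kexAB", "kexBC", "KeqAB", "KeqBC")
          else c("koff", "kBC", "kCB")
  if (!all(need %in% names(globalInit)))
    stop("globalInit must contain: ", paste(need, collapse = ", "))
  new("FitSpec", model = model, globalInit = globalInit[need],
      residueInit = residueInit, cribSet = as.integer(cribSet),
      tieR2BC = as.integer(tieR2BC), rateBounds = rateBounds,
      dwBound = dwBound, fitShiftF = fitShiftF)
}

#' Noise level of a CEST profile
#'
#' Second-difference noise estimator: a finite-difference filter removes the
#' smooth signal component, so
#' \deqn{\hat\sigma^2 = \sum_{i=2}^{N-1}(y_{i-1}-2y_i+y_{i+1})^2 / (6(N-2))}
#' on the offset-ordered intensities. Robust even for profiles with limited
#' baseline; a second difference annihilates linear trends exactly.
#'
#' @param profile a \linkS4class{CestProfile}
#' @param useMask restrict to masked-in points (default TRUE)
#' @return estimated per-point standard deviation
#' @export
estimateNoise <- function(profile, useMask = TRUE) {
  y <- profile@intensities
  if (useMask) y <- y[profile@mask]
  n <- length(y)
  if (n < 5) stop("need at least 5 points to estimate noise")
  d2 <- y[1:(n - 2)] - 2 * y[2:(n - 1)] + y[3:n]
  sqrt(sum(d2^2) / (6 * (n - 2)))
}

#' Pick candidate minor-state dips
#'
#' Finds local minima deeper than \code{threshold * sigma} below the local
#' baseline (median intensity), excluding a +/- B1 window around the major
#' dip (the deepest minimum, or an explicit major-state position). Automated
#' stand-in for interactive minor-state frequency selection.
#'
#' @param profile a \linkS4class{CestProfile}
#' @param threshold depth threshold in units of the noise level
#' @param sigma noise level; defaults to \code{\link{estimateNoise}}
#' @param majorShift optional major-state shift (ppm); defaults to the
#'   profile's deepest minimum
#' @return data.frame (offsetHz, shiftPpm, dwPpm, depth), sorted by depth;
#'   dwPpm is the dip-difference shift from the major state, the direct
#'   slow-exchange estimate of the minor-state Delta-omega
#' @export
pickDips <- function(profile, threshold = 5,
                     sigma = NULL, majorShift = NULL) {
  y <- profile@intensities
  off <- profile@offsets
  n <- length(y)
  if (n < 5) return(data.frame(offsetHz = numeric(), shiftPpm = numeric(),
                               dwPpm = numeric(), depth = numeric()))
  if (is.null(sigma))
    sigma <- if (any(profile@sigmas > 0)) max(median(profile@sigmas), 1e-12)
             else estimateNoise(profile, useMask = FALSE)
  expt <- profile@experiment
  baseline <- median(y)
  majorHz <- if (is.null(majorShift)) off[which.min(y)] else ppmToHz(majorShift, expt)
  # interior local minima
  isMin <- c(FALSE, y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n], FALSE)
  depth <- baseline - y
  keep <- isMin & depth > threshold * sigma
  # drop the major-dip window (aliasing-aware for DANTE)
  d <- off - majorHz
  if (expt@irradiation == "dante" && is.finite(expt@danteWindow)) {
    w <- expt@danteWindow
    d <- (d + w / 2) %% w - w / 2
  }
  keep <- keep & abs(d) > expt@B1
  res <- data.frame(offsetHz = off[keep],
                    shiftPpm = hzToPpm(off[keep], expt),
                    dwPpm = (off[keep] - majorHz) / expt@larmor15N,
                    depth = depth[keep])
  res[order(-res$depth), , drop = FALSE]
}

#' Deconvolve minor-state shift candidates across saturation profiles
#'
#' A dip in a D-CEST profile fixes the minor-state position only modulo the
#' DANTE window. Each dip is therefore expanded into its alias ladder
#' (dw + k window, |dw| <= maxDw), candidates are clustered across profiles,
#' and clusters are scored by the number of distinct profiles supporting
#' them: the true position recurs in every window (and in the unaliased CW
#' profile), whereas alias ghosts disagree between windows.
#'
#' @param profiles list of \linkS4class{CestProfile} of one residue
#' @param shiftF major-state shift (ppm)
#' @param threshold dip depth threshold in noise units
#' @param maxDw maximum |shift difference| considered (ppm)
#' @param clusterTol clustering tolerance (ppm)
#' @return data.frame(dwPpm, support, depth), sorted by support then depth
#' @export
dipCandidates <- function(profiles, shiftF, threshold = 3, maxDw = 7,
                          clusterTol = 0.15) {
  cand <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    dips <- tryCatch(pickDips(p, threshold = threshold, majorShift = shiftF),
                     error = function(e) NULL)
    if (is.null(dips) || nrow(dips) == 0) next
    e <- p@experiment
    for (j in seq_len(nrow(dips))) {
      if (e@irradiation == "dante" && is.finite(e@danteWindow)) {
        wPpm <- e@danteWindow / e@larmor15N
        # the dip offset and the aliased major position differ by dw mod window
        base <- (dips$offsetHz[j] - ppmToHz(shiftF, e)) / e@larmor15N
        ks <- seq(ceiling((-maxDw - base) / wPpm), floor((maxDw - base) / wPpm))
        dw <- base + ks * wPpm
      } else {
        dw <- dips$dwPpm[j]
      }
      dw <- dw[abs(dw) <= maxDw & abs(dw) > 0.05]
      if (length(dw))
        cand[[length(cand) + 1]] <- data.frame(dwPpm = dw, profile = i,
                                               depth = dips$depth[j])
    }
  }
  if (length(cand) == 0)
    return(data.frame(dwPpm = numeric(), support = integer(), depth = numeric()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$dwPpm), ]
  # single-linkage clustering on the ppm axis
  brk <- c(0, which(diff(cand$dwPpm) > clusterTol), nrow(cand))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1), function(g) {
    sub <- cand[(brk[g] + 1):brk[g + 1], ]
    data.frame(dwPpm = stats::weighted.mean(sub$dwPpm, sub$depth),
               support = length(unique(sub$profile)),
               depth = max(sub$depth))
  }))
  out[order(-out$support, -out$depth), , drop = FALSE]
}

# -- parameter codec ---------------------------------------------------------

# Fit-internal bookkeeping: maps a flat optimizer vector to (global scheme
# parameters, per-residue spin parameters), honouring scale (log10 for
# positives), bounds and tie rules. Built once per fit.
makeCodec <- function(dataset, spec, fixedGlobal = NULL, fixedResidues = FALSE) {
  info <- dataset@residueInfo
  excl <- info$residueId[info$excluded]
  profRes <- vapply(dataset@profiles, function(p) p@residueId, 1L)
  resIds <- intersect(spec@residueInit$residueId, setdiff(unique(profRes), excl))
  if (length(resIds) == 0) stop("no residues to fit")
  keepProf <- which(profRes %in% resIds)

  gnames <- names(spec@globalInit)
  gfree <- setdiff(gnames, names(fixedGlobal))
  ptab <- data.frame(name = gfree, residue = rep(NA_integer_, length(gfree)),
                     scale = rep("log", length(gfree)),
                     init = unname(spec@globalInit[gfree]),
                     lower = ifelse(grepl("^Keq", gfree), 1e-3, spec@rateBounds[1]),
                     upper = ifelse(grepl("^Keq", gfree), 1e3, spec@rateBounds[2]),
                     stringsAsFactors = FALSE)
  dwNames <- if (spec@model == "4site") c("dwFA", "dwFB", "dwFC") else c("dwFB", "dwFC")
  for (rid in if (fixedResidues) integer() else resIds) {
    row <- spec@residueInit[spec@residueInit$residueId == rid, ]
    relax <- c("R1F", "R2F", "R2B")
    if (!rid %in% spec@tieR2BC) relax <- c(relax, "R2C")
    if (spec@fitShiftF) {
      # the admissible window stays anchored to the original data-driven
      # estimate (shiftF0) so repeated refit rounds cannot walk the major
      # position away from the observed dip
      s0 <- if ("shiftF0" %in% names(row)) row$shiftF0[1] else row$shiftF[1]
      ptab <- rbind(ptab,
        data.frame(name = "shiftF", residue = rid, scale = "lin",
                   init = min(max(row$shiftF[1], s0 - 0.12), s0 + 0.12),
                   lower = s0 - 0.12, upper = s0 + 0.12,
                   stringsAsFactors = FALSE))
    }
    ptab <- rbind(ptab,
      data.frame(name = dwNames, residue = rid, scale = "lin",
                 init = as.numeric(row[1, dwNames]),
                 lower = -spec@dwBound, upper = spec@dwBound,
                 stringsAsFactors = FALSE),
      data.frame(name = relax, residue = rid, scale = "log",
                 init = as.numeric(row[1, relax]),
                 lower = spec@rateBounds[1], upper = spec@rateBounds[2],
                 stringsAsFactors = FALSE))
  }
  # weighted residual slices per kept profile
  wts <- lapply(dataset@profiles[keepProf], function(p) {
    s <- p@sigmas[p@mask]
    ifelse(s > 0, 1 / s, 1)
  })
  npts <- vapply(wts, length, 1L)
  ends <- cumsum(npts)
  resInit <- spec@residueInit[match(resIds, spec@residueInit$residueId), ]
  list(spec = spec, comp = dataset@composition, resInit = resInit,
       totalBound = boundFraction(dataset@composition),
       profiles = dataset@profiles[keepProf],
       profRes = profRes[keepProf], resIds = resIds,
       shiftF = setNames(spec@residueInit$shiftF,
                         spec@residueInit$residueId)[as.character(resIds)],
       shiftF0 = setNames(
         if ("shiftF0" %in% names(spec@residueInit)) spec@residueInit$shiftF0
         else spec@residueInit$shiftF,
         spec@residueInit$residueId)[as.character(resIds)],
       fixedGlobal = fixedGlobal, ptab = ptab, wts = wts,
       slices = mapply(function(a, b) seq.int(a, b),
                       c(1L, head(ends, -1L) + 1L), ends, SIMPLIFY = FALSE),
       nRes = sum(npts))
}

codecPack <- function(codec, values = codec$ptab$init) {
  ifelse(codec$ptab$scale == "log", log10(pmax(values, 1e-300)), values)
}

codecBounds <- function(codec) {
  isLog <- codec$ptab$scale == "log"
  lo <- codec$ptab$lower; hi <- codec$ptab$upper
  lo[isLog] <- log10(lo[isLog]); hi[isLog] <- log10(hi[isLog])
  list(lower = lo, upper = hi)
}

codecUnpack <- function(par, codec) {
  nat <- ifelse(codec$ptab$scale == "log", 10^par, par)
  tab <- codec$ptab
  g <- c(setNames(nat[is.na(tab$residue)], tab$name[is.na(tab$residue)]),
         codec$fixedGlobal)
  scheme <- schemeFromGlobals(codec$spec@model, g)
  pops <- partitionPopulations(codec$totalBound, scheme)
  # start from the initialization table (covers parameters held fixed), then
  # overwrite with the optimizer's current values
  ri <- codec$resInit
  pull <- function(nm) if (nm %in% names(ri)) as.numeric(ri[[nm]]) else
    rep(NA_real_, nrow(ri))
  resTab <- data.frame(residueId = codec$resIds,
                       shiftF = unname(codec$shiftF),
                       shiftF0 = unname(codec$shiftF0),
                       dwFA = pull("dwFA"), dwFB = pull("dwFB"),
                       dwFC = pull("dwFC"),
                       R1F = pull("R1F"), R2F = pull("R2F"), R2A = NA_real_,
                       R2B = pull("R2B"), R2C = pull("R2C"))
  for (k in seq_along(codec$resIds)) {
    rid <- codec$resIds[k]
    sel <- !is.na(tab$residue) & tab$residue == rid
    v <- setNames(nat[sel], tab$name[sel])
    for (nm in names(v)) resTab[k, nm] <- v[[nm]]
    if (rid %in% codec$spec@tieR2BC) resTab$R2C[k] <- resTab$R2B[k]
    if (codec$spec@model == "4site")
      resTab$R2A[k] <- if (rid %in% codec$spec@cribSet) resTab$R2B[k] else resTab$R2F[k]
  }
  list(global = g, scheme = scheme, pops = pops, resTab = resTab)
}

# Exchange scheme from the global-parameter vector; kon is not identified by
# the CEST data (the first step enters through the population constraint) and
# is set to 1, to be derived post hoc via deriveKon().
schemeFromGlobals <- function(model, g) {
  if (model == "4site") {
    kAB <- g[["kexAB"]] * g[["KeqAB"]] / (1 + g[["KeqAB"]])
    kBC <- g[["kexBC"]] * g[["KeqBC"]] / (1 + g[["KeqBC"]])
    ExchangeScheme("4site", kon = 1, koff = g[["koff"]],
                   kAB = kAB, kBA = g[["kexAB"]] - kAB,
                   kBC = kBC, kCB = g[["kexBC"]] - kBC)
  } else {
    ExchangeScheme("3site", kon = 1, koff = g[["koff"]],
                   kBC = g[["kBC"]], kCB = g[["kCB"]])
  }
}

spinFromRow <- function(row) {
  new("ResidueSpinSystem", residueId = as.integer(row$residueId),
      shiftF = row$shiftF, dwFA = as.numeric(row$dwFA), dwFB = row$dwFB,
      dwFC = row$dwFC, R1F = row$R1F, R2F = row$R2F,
      R2A = if (is.na(row$R2A)) row$R2F else as.numeric(row$R2A),
      R2B = row$R2B, R2C = row$R2C, ties = character())
}

# Weighted residual vector; `onlyResidues` restricts recomputation (used by
# the structured Jacobian), with `template` supplying the untouched entries.
codecResiduals <- function(par, codec, onlyResidues = NULL, template = NULL) {
  st <- codecUnpack(par, codec)
  out <- if (is.null(template)) numeric(codec$nRes) else template
  for (k in seq_along(codec$profiles)) {
    rid <- codec$profRes[k]
    if (!is.null(onlyResidues) && !rid %in% onlyResidues) next
    p <- codec$profiles[[k]]
    spin <- spinFromRow(st$resTab[match(rid, codec$resIds), ])
    m <- simulateIntensities(spin, st$scheme, st$pops, p@experiment)
    out[codec$slices[[k]]] <- (p@intensities[p@mask] - m[p@mask]) * codec$wts[[k]]
  }
  out
}

# Forward-difference Jacobian exploiting the block structure: residue-specific
# parameters only touch that residue's profiles.
codecJacobian <- function(par, codec, r0 = NULL) {
  if (is.null(r0)) r0 <- codecResiduals(par, codec)
  J <- matrix(0, length(r0), length(par))
  h <- 1e-6 * pmax(abs(par), 0.01)
  for (j in seq_along(par)) {
    pj <- par; pj[j] <- pj[j] + h[j]
    rid <- codec$ptab$residue[j]
    rj <- if (is.na(rid)) codecResiduals(pj, codec)
          else codecResiduals(pj, codec, onlyResidues = rid, template = r0)
    J[, j] <- (rj - r0) / h[j]
  }
  J
}

# -- fit engine --------------------------------------------------------------

# Bounded Levenberg-Marquardt with optional multi-start jitter (+/-50% on the
# global rate-like parameters) to escape local minima.
cestFitEngine <- function(dataset, spec, fixedGlobal = NULL,
                          fixedResidues = FALSE, nStarts = 1,
                          jitter = 0.5, jitterDw = 0, maxIter = 100,
                          ftol = 1e-8, seed = NULL) {
  codec <- makeCodec(dataset, spec, fixedGlobal, fixedResidues)
  b <- codecBounds(codec)
  p0 <- codecPack(codec)
  p0 <- pmin(pmax(p0, b$lower), b$upper)
  isGlobalRate <- is.na(codec$ptab$residue) & codec$ptab$scale == "log"
  isDw <- codec$ptab$scale == "lin" & codec$ptab$name != "shiftF"
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (s in seq_len(max(1, nStarts))) {
    p <- p0
    if (s > 1) {
      p[isGlobalRate] <- p[isGlobalRate] +
        log10(1 + runif(sum(isGlobalRate), -jitter, jitter))
      if (jitterDw > 0)
        p[isDw] <- p[isDw] + runif(sum(isDw), -jitterDw, jitterDw)
      p <- pmin(pmax(p, b$lower), b$upper)
    }
    fit <- tryCatch(
      withCallingHandlers(
        minpack.lm::nls.lm(
          par = p, lower = b$lower, upper = b$upper,
          fn = codecResiduals, jac = codecJacobian, codec = codec,
          control = minpack.lm::nls.lm.control(
            maxiter = maxIter, ftol = ftol, ptol = ftol, nprint = 0)),
        warning = function(w) {
          # iteration-cap warnings are routine in multi-start legs; the
          # convergence flag on the result carries the information
          if (grepl("maxiter", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    # flagged, non-converged result at the initial values
    st <- codecUnpack(p0, codec)
    return(buildFitResult(codec, p0, st, chisq = sum(codecResiduals(p0, codec)^2),
                          converged = FALSE, se = NULL))
  }
  # formal convergence, or a stalled objective (relative chi-square change
  # below 1e-6 per iteration) when the iteration cap was hit; only the first
  # niter trace entries are valid
  rt <- utils::head(best$rsstrace, max(best$niter, 1))
  stalled <- length(rt) >= 3 &&
    abs(diff(tail(rt, 2))) <= 1e-6 * max(tail(rt, 1), 1e-300)
  converged <- best$info %in% c(1, 2, 3, 4) || stalled
  st <- codecUnpack(best$par, codec)
  # covariance from J'J at the optimum (residuals already sigma-weighted)
  se <- tryCatch({
    J <- codecJacobian(best$par, codec)
    cv <- chol2inv(chol(crossprod(J)))
    sqrt(pmax(diag(cv), 0))
  }, error = function(e) NULL)
  buildFitResult(codec, best$par, st, chisq = best$deviance,
                 converged = converged, se = se)
}

buildFitResult <- function(codec, par, st, chisq, converged, se) {
  tab <- codec$ptab
  isG <- is.na(tab$residue)
  gse <- rep(NA_real_, length(st$global))
  names(gse) <- names(st$global)
  if (!is.null(se)) {
    nat <- ifelse(tab$scale == "log", 10^par, par)
    seNat <- ifelse(tab$scale == "log", log(10) * nat * se, se)
    gse[tab$name[isG]] <- seNat[isG]
  }
  resid <- lapply(seq_along(codec$profiles), function(k) {
    r <- codecResiduals(par, codec, onlyResidues = codec$profRes[k],
                        template = numeric(codec$nRes))
    r[codec$slices[[k]]]
  })
  new("GlobalFitResult", model = codec$spec@model, globalPar = st$global,
      globalSE = gse, residuePar = st$resTab, chisq = chisq,
      nPoints = codec$nRes, nPar = length(par), residuals = resid,
      converged = converged, composition = codec$comp)
}

#' @rdname globalParams
#' @export
setMethod("globalParams", "GlobalFitResult", function(object) object@globalPar)

#' @rdname chiSquare
#' @export
setMethod("chiSquare", "GlobalFitResult", function(object) object@chisq)

#' @rdname residueParams
#' @export
setMethod("residueParams", "GlobalFitResult", function(object) object@residuePar)

setMethod("show", "GlobalFitResult", function(object) {
  cat(sprintf("%s global fit: chi2 = %.4g over %d points, %d parameters (dof %d)%s\n",
              object@model, object@chisq, object@nPoints, object@nPar,
              object@nPoints - object@nPar,
              if (object@converged) "" else " [NOT CONVERGED]"))
  g <- object@globalPar
  for (nm in names(g))
    cat(sprintf("  %-6s = %.4g +/- %.3g\n", nm, g[[nm]], object@globalSE[[nm]]))
  invisible(NULL)
})

#' Residue-specific 3-site fit across B1 fields
#'
#' First analysis stage: one residue, all its profiles, 3-site exchange model
#' with the bound-population sum fixed from the composition and the
#' R2B = R2C tie applied. Optimizes koff, kBC, kCB, dwFB, dwFC, R1F, R2F and
#' R2B(=R2C) by bounded Levenberg-Marquardt with multi-start jitter.
#'
#' @param dataset a \linkS4class{CestDataset} (profiles of other residues are
#'   ignored)
#' @param residueId the residue to fit
#' @param init optional named initial values overriding the defaults
#'   (koff, kBC, kCB, dwFB, dwFC, R1F, R2F, R2B)
#' @param shiftF major-state shift (ppm); default from profile minima
#' @param nStarts multi-start count
#' @param seed RNG seed for the start jitter
#' @return a \linkS4class{GlobalFitResult} restricted to one residue
#' @export
fitResidue3Site <- function(dataset, residueId, init = NULL, shiftF = NULL,
                            nStarts = 5, seed = NULL) {
  prof <- datasetProfiles(dataset, residueId)
  if (length(prof) == 0) stop("no profiles for residue ", residueId)
  if (is.null(shiftF)) shiftF <- inferShiftF(prof)
  defaults <- defaultResidueInit(prof, shiftF)
  if (is.null(init) || !all(c("dwFB", "dwFC") %in% names(init))) {
    scan <- residueDwScan(prof, shiftF, dataset@composition,
                          defaults[c("R1F", "R2F", "R2B")])
    if (!is.null(scan)) {
      defaults[["dwFB"]] <- scan$dwFB
      defaults[["dwFC"]] <- scan$dwFC
      defaults[["R2B"]] <- scan$R2B
    }
  }
  gi <- c(koff = 50, kBC = 100, kCB = 100)
  if (!is.null(init)) {
    gi[intersect(names(init), names(gi))] <- init[intersect(names(init), names(gi))]
    for (nm in intersect(names(init), names(defaults)))
      defaults[[nm]] <- init[[nm]]
  }
  ri <- data.frame(residueId = residueId, shiftF = shiftF,
                   dwFA = NA_real_, dwFB = defaults[["dwFB"]],
                   dwFC = defaults[["dwFC"]], R1F = defaults[["R1F"]],
                   R2F = defaults[["R2F"]], R2B = defaults[["R2B"]],
                   R2C = defaults[["R2B"]])
  spec <- FitSpec("3site", gi, ri, tieR2BC = residueId)
  sub <- CestDataset(prof, dataset@composition,
                     dataset@residueInfo[dataset@residueInfo$residueId == residueId, ])
  cestFitEngine(sub, spec, nStarts = nStarts, jitterDw = 0.4, seed = seed)
}

datasetProfiles <- function(dataset, residueId) {
  Filter(function(p) p@residueId %in% residueId, dataset@profiles)
}

# Sub-grid dip position by parabolic interpolation through the minimum and
# its neighbours; falls back to the grid point at profile edges.
parabolicMinimum <- function(off, y) {
  i <- which.min(y)
  if (i == 1 || i == length(y)) return(off[i])
  d1 <- y[i - 1] - y[i]; d2 <- y[i + 1] - y[i]
  if (d1 + d2 <= 0) return(off[i])
  off[i] + 0.5 * (off[i + 1] - off[i]) * (d1 - d2) / (d1 + d2)
}

# Major-state shift: coarse estimate from the unaliased CW profile, refined
# against the finest-stepped DANTE profile by picking the alias-ladder
# position closest to the coarse estimate.
inferShiftF <- function(profiles) {
  cw <- Filter(function(p) p@experiment@irradiation == "cw", profiles)
  p <- if (length(cw)) cw[[which.max(vapply(cw, function(q) q@experiment@B1, 0))]]
       else profiles[[1]]
  coarseHz <- parabolicMinimum(p@offsets, p@intensities)
  da <- Filter(function(q) q@experiment@irradiation == "dante" &&
                 is.finite(q@experiment@danteWindow), profiles)
  if (length(da) == 0 || p@experiment@irradiation == "dante")
    return(hzToPpm(coarseHz, p@experiment))
  steps <- vapply(da, function(q) mean(diff(q@offsets)), 0)
  q <- da[[which.min(steps)]]
  w <- q@experiment@danteWindow
  aliasHz <- parabolicMinimum(q@offsets, q@intensities)
  k <- round((coarseHz - aliasHz) / w)
  fineHz <- aliasHz + k * w
  # the refinement is self-consistent as long as the correction stays well
  # inside the alias half-window (the coarse estimate can be skewed by up to
  # half a CW grid step when minor dips lean on the major one)
  if (abs(fineHz - coarseHz) > 0.45 * w)
    return(hzToPpm(coarseHz, p@experiment))
  hzToPpm(fineHz, q@experiment)
}

# Robust (dwFB, dwFC) starting pair: coarse chi-square scan of the forward
# model over pairs of alias-ladder dip candidates at the supplied (nominal or
# fitted) global rates. Dip positions dominate the chi-square, so the scan is
# insensitive to the rates; it resolves both the alias ambiguity and the B/C
# ordering that defeat per-profile dip picking. For hierarchically folding
# residues the intermediate may sit anywhere between the free and bound
# positions, so fractional positions f * dwFC are scanned for dwFB as well.
residueDwScan <- function(profiles, shiftF, comp, relax,
                          globalPar = c(koff = 50, kBC = 75, kCB = 75),
                          model = "3site", crib = FALSE,
                          fracB = c(0.5, 1), R2Bgrid = c(12, 30)) {
  cands <- dipCandidates(profiles, shiftF, threshold = 3, clusterTol = 0.1)
  # dw = 0 is always a candidate (residues without resolvable dips must be
  # able to start from the no-shift solution); +/- 0.3 ppm satellites around
  # each cluster let the scan split two states hiding under one broad dip
  base <- cands$dwPpm[seq_len(min(nrow(cands), 5))]
  dwC <- unique(round(c(0, base, base + 0.3, base - 0.3), 3))
  dwB <- unique(round(c(dwC, as.vector(outer(fracB, base))), 3))
  sch <- schemeFromGlobals(model, globalPar)
  pops <- partitionPopulations(boundFraction(comp), sch)
  # scanning needs position discrimination, not full coverage: the unaliased
  # CW profiles plus the two widest DANTE windows suffice
  cw <- Filter(function(p) p@experiment@irradiation == "cw", profiles)
  da <- Filter(function(p) p@experiment@irradiation == "dante", profiles)
  if (length(da) > 2) {
    wins <- vapply(da, function(p) p@experiment@danteWindow, 0)
    da <- da[order(-wins)[1:2]]
  }
  scanProf <- c(cw, da)
  # relaxation of the minor states is unknown at scan time (and a previous
  # bad fit may have left absurd values); scan a small nominal grid instead
  best <- NULL
  for (R2B in R2Bgrid) {
    for (i in seq_len(length(dwB) * length(dwC))) {
      b <- dwB[(i - 1) %% length(dwB) + 1]
      cc <- dwC[(i - 1) %/% length(dwB) + 1]
      dwFA <- if (model != "4site") NA_real_ else if (crib) b else 0
      spin <- new("ResidueSpinSystem", residueId = profiles[[1]]@residueId,
                  shiftF = shiftF, dwFA = dwFA, dwFB = b, dwFC = cc,
                  R1F = relax[["R1F"]], R2F = max(relax[["R2F"]], 4),
                  R2A = if (crib) R2B else max(relax[["R2F"]], 4),
                  R2B = R2B, R2C = R2B, ties = character())
      chi <- 0
      for (p in scanProf) {
        m <- simulateIntensities(spin, sch, pops, p@experiment)
        w <- ifelse(p@sigmas > 0, 1 / p@sigmas, 1)
        chi <- chi + sum(((p@intensities - m) * w)[p@mask]^2)
      }
      if (is.null(best) || chi < best$chi)
        best <- list(dwFB = b, dwFC = cc, R2B = R2B, chi = chi)
    }
  }
  best
}

#' Refine poorly fitting residues of a global fit
#'
#' Residues whose per-residue reduced chi-square exceeds
#' \code{factor} times the median are re-initialized by a dip-candidate scan
#' (with the global parameters held at their fitted values), their
#' residue-specific parameters re-optimized locally, and the improved values
#' returned as an updated residue-initialization table. Used between global
#' fit rounds to escape residue-level local minima.
#'
#' @param dataset a \linkS4class{CestDataset}
#' @param spec the \linkS4class{FitSpec} of the global fit
#' @param fit the current \linkS4class{GlobalFitResult}
#' @param factor misfit threshold relative to the median reduced chi-square
#' @param maxIter iteration cap of the local refits
#' @return list(residueInit, refined = residue ids touched)
#' @export
refineResidueFits <- function(dataset, spec, fit, factor = 2, maxIter = 60) {
  ri <- resInitFromFit(fit)
  # per-residue chi-square per point
  ids <- vapply(dataset@profiles, function(p) p@residueId, 1L)
  ids <- ids[ids %in% ri$residueId]   # align with the fit's profile order
  chi <- vapply(fit@residuals, function(r) sum(r^2), 0)
  npt <- vapply(fit@residuals, length, 1L)
  perRes <- vapply(ri$residueId, function(rid)
    sum(chi[ids == rid]) / max(sum(npt[ids == rid]), 1), 0)
  bad <- ri$residueId[perRes > factor * median(perRes) & perRes > 2]
  if (length(bad) == 0) return(list(residueInit = ri, refined = integer()))
  gp <- fit@globalPar[names(spec@globalInit)]
  for (rid in bad) {
    prof <- datasetProfiles(dataset, rid)
    row <- ri[ri$residueId == rid, ]
    crib <- rid %in% spec@cribSet
    scan <- residueDwScan(prof, row$shiftF, dataset@composition,
                          c(R1F = row$R1F, R2F = row$R2F, R2B = row$R2B),
                          globalPar = gp, model = spec@model, crib = crib)
    if (is.null(scan)) next
    row$dwFB <- scan$dwFB; row$dwFC <- scan$dwFC
    row$R2B <- scan$R2B; row$R2C <- scan$R2B
    if (spec@model == "4site") row$dwFA <- if (crib) scan$dwFB else 0
    # local re-optimization of this residue only, globals fixed
    sub <- CestDataset(prof, dataset@composition,
                       dataset@residueInfo[dataset@residueInfo$residueId == rid, ])
    sp <- FitSpec(spec@model, gp, row, cribSet = intersect(spec@cribSet, rid),
                  tieR2BC = intersect(spec@tieR2BC, rid),
                  rateBounds = spec@rateBounds, dwBound = spec@dwBound)
    loc <- tryCatch(cestFitEngine(sub, sp, fixedGlobal = gp, nStarts = 3,
                                  jitterDw = 0.3, maxIter = maxIter),
                    error = function(e) NULL)
    if (!is.null(loc)) {
      upd <- resInitFromFit(loc)
      ri[ri$residueId == rid, names(upd)] <- upd
    } else {
      ri[ri$residueId == rid, ] <- row
    }
  }
  list(residueInit = ri, refined = bad)
}

# Starting values from the data: the far-off-resonance baseline fixes R1F
# (baseline = exp(-R1F Tsat)); alias-deconvolved dip candidates initialize
# dwFB (closer to F) and dwFC (farther), mirroring the initial minor-state
# assignment convention.
defaultResidueInit <- function(profiles, shiftF) {
  cw <- Filter(function(p) p@experiment@irradiation == "cw", profiles)
  p <- if (length(cw)) cw[[which.max(vapply(cw, function(q) q@experiment@B1, 0))]]
       else profiles[[1]]
  Tsat <- p@experiment@Tsat
  far <- order(-abs(p@offsets - ppmToHz(shiftF, p@experiment)))[1:min(4, length(p@offsets))]
  base <- mean(p@intensities[far])
  R1F <- if (base > 0 && base < 1 && Tsat > 0) -log(base) / Tsat else 1.5
  cands <- dipCandidates(profiles, shiftF, threshold = 3)
  good <- cands[cands$support >= 2, , drop = FALSE]
  if (nrow(good) < 2) good <- cands
  if (nrow(good) >= 2) {
    two <- good[1:2, ]
    two <- two[order(abs(two$dwPpm)), ]
    dwFB <- two$dwPpm[1]; dwFC <- two$dwPpm[2]
  } else if (nrow(good) == 1) {
    dwFB <- good$dwPpm[1]; dwFC <- good$dwPpm[1]
  } else {
    dwFB <- 0.5; dwFC <- 1
  }
  c(dwFB = dwFB, dwFC = dwFC, R1F = max(R1F, 0.05), R2F = 5, R2B = 20)
}

#' Assign resolved minor dips to the intermediate and bound states
#'
#' Fits the residue 3-site with the dip closest to the major state assigned
#' to the intermediate B and the farthest to the complex C, then refits with
#' the swapped assignment; the original assignment is accepted if the swap
#' increases the residuals or reverts to the original configuration.
#'
#' @inheritParams fitResidue3Site
#' @param dwB,dwC candidate shift differences (ppm) of the two resolved minor
#'   dips; by default taken from \code{\link{pickDips}}
#' @param revertTol relative shift-difference tolerance for declaring that
#'   the swapped fit reverted to the original assignment
#' @return list with elements fit, fitSwapped, accepted ("original" or
#'   "swapped"), reverted, ambiguous, pB, pC
#' @export
assignMinorStates <- function(dataset, residueId, dwB = NULL, dwC = NULL,
                              shiftF = NULL, nStarts = 3, seed = NULL,
                              revertTol = 0.15) {
  prof <- datasetProfiles(dataset, residueId)
  if (is.null(shiftF)) shiftF <- inferShiftF(prof)
  if (is.null(dwB) || is.null(dwC)) {
    cands <- dipCandidates(prof, shiftF, threshold = 3)
    cands <- cands[cands$support >= 2, , drop = FALSE]
    if (nrow(cands) < 2)
      stop("residue has fewer than 2 resolved minor dips; assignment deferred ",
           "to the global fit")
    two <- cands[1:2, ]
    two <- two[order(abs(two$dwPpm)), ]
    dwB <- two$dwPpm[1]; dwC <- two$dwPpm[2]
  }
  if (abs(abs(dwB) - abs(dwC)) < 1e-6 * max(1, abs(dwC)))
    return(list(fit = NULL, fitSwapped = NULL, accepted = NA,
                reverted = NA, ambiguous = TRUE, pB = NA, pC = NA))
  orig <- fitResidue3Site(dataset, residueId, init = c(dwFB = dwB, dwFC = dwC),
                          shiftF = shiftF, nStarts = nStarts, seed = seed)
  swap <- fitResidue3Site(dataset, residueId, init = c(dwFB = dwC, dwFC = dwB),
                          shiftF = shiftF, nStarts = nStarts, seed = seed)
  # did the swapped fit crawl back to the original configuration?
  rs <- swap@residuePar
  reverted <- (abs(rs$dwFB - dwB) < revertTol * max(1, abs(dwB))) &&
              (abs(rs$dwFC - dwC) < revertTol * max(1, abs(dwC)))
  accepted <- if (swap@chisq >= orig@chisq || reverted) "original" else "swapped"
  fit <- if (accepted == "original") orig else swap
  sch <- schemeFromGlobals("3site", fit@globalPar)
  pops <- populations(partitionPopulations(boundFraction(dataset@composition), sch))
  list(fit = orig, fitSwapped = swap, accepted = accepted, reverted = reverted,
       ambiguous = FALSE, pB = pops[["B"]], pC = pops[["C"]])
}

#' Global fit of a CEST dataset
#'
#' Minimizes the summed masked chi-square across all residues and B1 fields
#' over the model's global exchange parameters and the residue-specific shift
#' differences and relaxation rates, with the bound-state population sum
#' constrained by the composition. For the 4-site model, R2A is tied to R2B
#' inside the anchoring-motif set and to R2F outside it.
#'
#' @param dataset a \linkS4class{CestDataset}
#' @param spec a \linkS4class{FitSpec}
#' @param nStarts multi-start count (jitter on the global rates)
#' @param maxIter Levenberg-Marquardt iteration cap
#' @param seed RNG seed for start jitter
#' @return a \linkS4class{GlobalFitResult}
#' @export
fitGlobal <- function(dataset, spec, nStarts = 1, maxIter = 100, seed = NULL,
                      ftol = 1e-8) {
  cestFitEngine(dataset, spec, nStarts = nStarts, maxIter = maxIter,
                seed = seed, ftol = ftol)
}

#' Staged global fit: branch-and-alternate warm start, then the joint fit
#'
#' The joint least-squares problem couples a handful of global exchange
#' parameters to several parameters per residue, and the two compartments can
#' compensate each other (a wrong population split is absorbed by minor-state
#' transverse rates), creating broad correlated local minima. This driver
#' therefore (i) branches over a coarse grid of the anchored-intermediate
#' equilibrium constant KeqAB -- the one global parameter the 3-site stage
#' provides no information about; (ii) within each branch alternates a
#' globals-only fit (residue parameters frozen) with per-residue
#' re-initialization (dip-candidate scan at the current globals) and local
#' refits (globals frozen); and (iii) releases all parameters for the final
#' joint Levenberg-Marquardt fit, started from the best branch.
#' For the 3-site model there is nothing to branch over and a single
#' alternation cycle precedes the joint fit.
#'
#' @inheritParams fitGlobal
#' @param branches KeqAB branch values (4-site only)
#' @param cycles alternation cycles per branch
#' @return a \linkS4class{GlobalFitResult}
#' @export
fitGlobalStaged <- function(dataset, spec, branches = c(1, 0.5, 2),
                            cycles = 1, maxIter = 150, seed = NULL,
                            gateChiPerPoint = 2) {
  if (spec@model != "4site") branches <- NA
  fit <- NULL
  for (br in branches) {
    gi <- spec@globalInit
    fixed <- NULL
    if (!is.na(br)) {
      gi[["KeqAB"]] <- br
      fixed <- c(KeqAB = br)
    }
    ri <- spec@residueInit
    for (cy in seq_len(cycles)) {
      sp <- respec(spec, gi, ri)
      gfit <- tryCatch(
        cestFitEngine(dataset, sp, fixedGlobal = fixed, fixedResidues = TRUE,
                      maxIter = 50, seed = seed),
        error = function(e) NULL)
      if (!is.null(gfit)) gi <- gfit@globalPar[names(gi)]
      ri <- alternateResidues(dataset, spec, gi, ri, rescan = (cy == 1))
    }
    cand <- cestFitEngine(dataset, respec(spec, gi, ri), maxIter = maxIter)
    if (is.null(fit) || cand@chisq < fit@chisq) fit <- cand
    # a joint fit consistent with the noise needs no alternative branches --
    # unless a minor-state R2 collapsed toward zero, the signature of a wrong
    # population split absorbed by the relaxation parameters
    collapsed <- any(fit@residuePar$R2B < 1 & fit@residuePar$R2F > 2)
    if (fit@chisq / fit@nPoints < gateChiPerPoint && !collapsed) break
  }
  # final sweep: swap-test / re-polish residues at the fitted globals, and
  # re-run the joint fit if any residue escaped a local minimum
  gi <- fit@globalPar[names(spec@globalInit)]
  ri2 <- alternateResidues(dataset, spec, gi, resInitFromFit(fit),
                           rescan = FALSE, nStarts = 1, swapTest = TRUE)
  codec <- makeCodec(dataset, respec(spec, gi, ri2), fixedResidues = TRUE)
  chi2 <- sum(codecResiduals(codecPack(codec), codec)^2)
  if (chi2 < fit@chisq - 2)
    fit <- cestFitEngine(dataset, respec(spec, gi, ri2), maxIter = maxIter)
  fit
}

respec <- function(spec, gi, ri) {
  FitSpec(spec@model, gi, ri, cribSet = spec@cribSet, tieR2BC = spec@tieR2BC,
          rateBounds = spec@rateBounds, dwBound = spec@dwBound,
          fitShiftF = spec@fitShiftF)
}

# one sweep of per-residue local fits with the globals frozen; optionally
# re-initializes each residue's shift differences by the dip-candidate scan
# and/or tries the B/C label swap
alternateResidues <- function(dataset, spec, gi, ri, rescan = TRUE,
                              nStarts = 2, swapTest = FALSE, tieBC = rescan) {
  for (rid in ri$residueId) {
    prof <- datasetProfiles(dataset, rid)
    if (length(prof) == 0) next
    row <- ri[ri$residueId == rid, , drop = FALSE]
    crib <- rid %in% spec@cribSet
    if (rescan) {
      scan <- tryCatch(
        residueDwScan(prof, row$shiftF, dataset@composition,
                      c(R1F = row$R1F, R2F = row$R2F, R2B = row$R2B),
                      globalPar = gi, model = spec@model, crib = crib),
        error = function(e) NULL)
      if (!is.null(scan)) {
        row$dwFB <- scan$dwFB; row$dwFC <- scan$dwFC
        row$R2B <- scan$R2B; row$R2C <- scan$R2B
        if (spec@model == "4site") row$dwFA <- if (crib) scan$dwFB else 0
      }
    }
    sub <- CestDataset(prof, dataset@composition,
                       dataset@residueInfo[
                         dataset@residueInfo$residueId == rid, , drop = FALSE])
    # during warm-up sweeps the R2B = R2C tie closes the channel by which a
    # wrong population split gets absorbed into split minor-state R2 values;
    # the final joint fit releases it
    spR <- FitSpec(spec@model, gi, row, cribSet = intersect(spec@cribSet, rid),
                   tieR2BC = if (tieBC) rid else intersect(spec@tieR2BC, rid),
                   rateBounds = spec@rateBounds, dwBound = spec@dwBound,
                   fitShiftF = spec@fitShiftF)
    loc <- tryCatch(
      cestFitEngine(sub, spR, fixedGlobal = gi, nStarts = nStarts,
                    jitterDw = 0.3, maxIter = 60),
      error = function(e) NULL)
    # swap test: when both minor states carry comparable shifts the B/C
    # labelling is nearly degenerate; refit with the assignment exchanged
    # and keep whichever describes the data better
    if (!is.null(loc)) {
      rp <- loc@residuePar
      if (swapTest && abs(rp$dwFB) > 0.3 && abs(rp$dwFC) > 0.3 &&
          abs(rp$dwFB - rp$dwFC) > 1e-6) {
        rowS <- resInitFromFit(loc)
        tmp <- rowS$dwFB; rowS$dwFB <- rowS$dwFC; rowS$dwFC <- tmp
        if (spec@model == "4site" && crib) rowS$dwFA <- rowS$dwFB
        spS <- FitSpec(spec@model, gi, rowS,
                       cribSet = intersect(spec@cribSet, rid),
                       tieR2BC = intersect(spec@tieR2BC, rid),
                       rateBounds = spec@rateBounds, dwBound = spec@dwBound,
                       fitShiftF = spec@fitShiftF)
        locS <- tryCatch(
          cestFitEngine(sub, spS, fixedGlobal = gi, maxIter = 60),
          error = function(e) NULL)
        if (!is.null(locS) && locS@chisq < loc@chisq) loc <- locS
      }
      upd <- resInitFromFit(loc)
      ri[ri$residueId == rid, names(upd)] <- upd
    } else {
      ri[ri$residueId == rid, names(row)] <- row
    }
  }
  ri
}

#' Derive the bimolecular association rate from a constrained fit
#'
#' kon is not directly identified by the CEST data (the first step enters the
#' likelihood only through the constrained populations and koff); it follows
#' from detailed balance: kon = koff (p_first/p_F) / [partner_free], with the
#' free-partner concentration from the mass-balance quadratic.
#'
#' @param result a \linkS4class{GlobalFitResult}
#' @return kon in M-1 s-1
#' @export
deriveKon <- function(result) {
  comp <- result@composition
  fb <- boundFraction(comp)
  sch <- schemeFromGlobals(result@model, result@globalPar)
  p <- populations(partitionPopulations(fb, sch))
  Rfree_uM <- comp@R0 - fb * comp@P0
  if (Rfree_uM <= 0) stop("no free partner at this composition")
  result@globalPar[["koff"]] * (p[[2]] / p[[1]]) / (Rfree_uM * 1e-6)
}

#' F-test comparison of nested CEST exchange models
#'
#' \deqn{F = \frac{(\chi^2_3 - \chi^2_4)/\Delta k}{\chi^2_4/dof_4}}
#' with Delta-k the parameter-count difference; the 4-site model is preferred
#' when p < alpha. If the larger model fits worse, the decision is "3site"
#' with p = 1.
#'
#' @param res3,res4 \linkS4class{GlobalFitResult} of the nested (3-site) and
#'   encompassing (4-site) models on identical data and masks
#' @param alpha significance level
#' @return list(F, df1, df2, p, decision)
#' @export
compareModels <- function(res3, res4, alpha = 0.05) {
  if (res3@nPoints != res4@nPoints)
    stop("models were not fit on identical data")
  dk <- res4@nPar - res3@nPar
  dof4 <- res4@nPoints - res4@nPar
  if (res4@chisq >= res3@chisq)
    return(list(F = 0, df1 = dk, df2 = dof4, p = 1, decision = "3site"))
  Fstat <- ((res3@chisq - res4@chisq) / dk) / (res4@chisq / dof4)
  p <- pf(Fstat, dk, dof4, lower.tail = FALSE)
  list(F = Fstat, df1 = dk, df2 = dof4, p = p,
       decision = if (p < alpha) "4site" else "3site")
}

#' Bootstrap uncertainties of the global parameters
#'
#' Builds replicate datasets by resampling each profile's points with
#' replacement (profile sizes preserved), refits each from the point
#' estimate, and reports 68% percentile intervals of the replicate
#' distributions. Non-converging replicates are dropped and counted.
#'
#' @param dataset a \linkS4class{CestDataset}
#' @param spec a \linkS4class{FitSpec}
#' @param pointFit converged point fit supplying starting values
#' @param n number of replicates
#' @param seed RNG seed
#' @param maxIter iteration cap per replicate
#' @return a \linkS4class{BootstrapSummary}
#' @export
bootstrapGlobal <- function(dataset, spec, pointFit, n = 300, seed = 1,
                            maxIter = 40) {
  gnames <- names(spec@globalInit)
  point <- pointFit@globalPar[gnames]
  if (n == 0)
    return(new("BootstrapSummary", nReplicates = 0L,
               replicates = matrix(numeric(), 0, length(gnames),
                                   dimnames = list(NULL, gnames)),
               ci68 = matrix(NA_real_, 2, length(gnames),
                             dimnames = list(c("16%", "84%"), gnames)),
               pointEstimate = point, nDropped = 0L, seed = as.integer(seed)))
  # start replicates from the point estimate
  spec2 <- FitSpec(spec@model, point,
                   resInitFromFit(pointFit), cribSet = spec@cribSet,
                   tieR2BC = spec@tieR2BC, rateBounds = spec@rateBounds,
                   dwBound = spec@dwBound)
  set.seed(seed)
  reps <- matrix(NA_real_, n, length(gnames), dimnames = list(NULL, gnames))
  dropped <- 0L
  for (b in seq_len(n)) {
    prof <- lapply(dataset@profiles, resampleProfile)
    ds <- new("CestDataset", profiles = prof, composition = dataset@composition,
              residueInfo = dataset@residueInfo)
    # replicates start at the point optimum; a relaxed objective tolerance
    # stops the crawl along sloppy directions that the replicate spread
    # quantifies anyway
    fit <- tryCatch(cestFitEngine(ds, spec2, nStarts = 1, maxIter = maxIter,
                                  ftol = 1e-6),
                    error = function(e) NULL)
    if (is.null(fit) || !fit@converged) { dropped <- dropped + 1L; next }
    reps[b, ] <- fit@globalPar[gnames]
  }
  if (dropped > 0.2 * n)
    warning(sprintf("%d of %d bootstrap replicates failed to converge", dropped, n))
  ok <- reps[stats::complete.cases(reps), , drop = FALSE]
  ci <- apply(ok, 2, quantile, probs = c(0.16, 0.84), names = FALSE)
  rownames(ci) <- c("16%", "84%")
  new("BootstrapSummary", nReplicates = as.integer(n), replicates = ok,
      ci68 = ci, pointEstimate = point, nDropped = dropped,
      seed = as.integer(seed))
}

# point resampling with replacement, profile length retained; offsets must
# stay ordered, so replicates reweight points via duplication counts instead
# of reordering (equivalent chi-square contribution)
resampleProfile <- function(p) {
  n <- length(p@offsets)
  cnt <- tabulate(sample.int(n, n, replace = TRUE), n)
  # multiplicity-weighted representation of the resampled multiset: identical
  # chi-square to literal duplication, but keeps the offset grid valid
  new("CestProfile", residueId = p@residueId, experiment = p@experiment,
      offsets = p@offsets, intensities = p@intensities,
      sigmas = p@sigmas / sqrt(pmax(cnt, 1)),
      mask = p@mask & cnt > 0)
}

resInitFromFit <- function(fit) {
  tab <- fit@residuePar
  keep <- intersect(c("residueId", "shiftF", "shiftF0", "dwFA", "dwFB", "dwFC",
                      "R1F", "R2F", "R2B", "R2C"), names(tab))
  tab[, keep]
}

setMethod("show", "BootstrapSummary", function(object) {
  cat(sprintf("Bootstrap: %d replicates (%d dropped), seed %d\n",
              object@nReplicates, object@nDropped, object@seed))
  if (nrow(object@replicates)) {
    for (nm in colnames(object@ci68))
      cat(sprintf("  %-6s = %.4g  [%.4g, %.4g] (68%%)\n", nm,
                  object@pointEstimate[[nm]], object@ci68[1, nm], object@ci68[2, nm]))
  }
  invisible(NULL)
})

#' Search for the anchoring-motif residue boundaries
#'
#' Systematically varies the (lower, upper) residue limits inside a candidate
#' range; each combination defines the motif set (assignable residues within
#' the limits), a global 4-site fit is run, and the subset with minimal total
#' residuals is returned along with the full residual trace.
#'
#' @param dataset a \linkS4class{CestDataset}
#' @param spec a 4-site \linkS4class{FitSpec} (its cribSet is overridden per
#'   combination)
#' @param candidateRange integer vector c(lo, hi) of residue limits to scan
#' @param maxIter iteration cap per fit
#' @return list(cribSet, chisq, trace = data.frame(lower, upper, chisq),
#'   noAnchoredState)
#' @export
searchCribBoundary <- function(dataset, spec, candidateRange, maxIter = 60) {
  info <- dataset@residueInfo
  cand <- info$residueId[info$assignable & !info$excluded &
                         info$residueId >= candidateRange[1] &
                         info$residueId <= candidateRange[2]]
  if (length(cand) == 0) stop("no candidate residues in range")
  lims <- expand.grid(lower = cand, upper = cand)
  lims <- lims[lims$lower <= lims$upper, ]
  trace <- data.frame(lower = lims$lower, upper = lims$upper, chisq = NA_real_)
  best <- NULL
  for (i in seq_len(nrow(lims))) {
    cs <- cand[cand >= lims$lower[i] & cand <= lims$upper[i]]
    sp <- FitSpec("4site", spec@globalInit, spec@residueInit, cribSet = cs,
                  tieR2BC = spec@tieR2BC, rateBounds = spec@rateBounds,
                  dwBound = spec@dwBound)
    fit <- cestFitEngine(dataset, sp, nStarts = 1, maxIter = maxIter)
    trace$chisq[i] <- fit@chisq
    if (is.null(best) || fit@chisq < best$chisq)
      best <- list(cribSet = cs, chisq = fit@chisq, fit = fit)
  }
  # does the best anchored model beat a no-anchored-state fit significantly?
  sp0 <- FitSpec("4site", spec@globalInit, spec@residueInit, cribSet = integer(),
                 tieR2BC = spec@tieR2BC, rateBounds = spec@rateBounds,
                 dwBound = spec@dwBound)
  fit0 <- cestFitEngine(dataset, sp0, nStarts = 1, maxIter = maxIter)
  none <- fit0@chisq <= min(trace$chisq, na.rm = TRUE) * (1 + 1e-6)
  list(cribSet = if (none) integer() else best$cribSet,
       chisq = if (none) fit0@chisq else best$chisq,
       trace = trace, noAnchoredState = none)
}

#' Profile-likelihood grid search over the step exchange rates
#'
#' Fixes (kexAB, kexBC) at each node of a grid and re-optimizes all remaining
#' parameters, returning the chi-square surface. The surface minimum should
#' fall within one grid cell of the unconstrained optimum.
#'
#' @param dataset a \linkS4class{CestDataset}
#' @param spec a 4-site \linkS4class{FitSpec}
#' @param kexABGrid,kexBCGrid grid node values (s-1)
#' @param maxIter iteration cap per node
#' @return data.frame(kexAB, kexBC, chisq)
#' @export
gridSearch <- function(dataset, spec, kexABGrid, kexBCGrid, maxIter = 60) {
  grid <- expand.grid(kexAB = kexABGrid, kexBC = kexBCGrid)
  grid$chisq <- NA_real_
  for (i in seq_len(nrow(grid))) {
    fit <- cestFitEngine(dataset, spec,
                         fixedGlobal = c(kexAB = grid$kexAB[i],
                                         kexBC = grid$kexBC[i]),
                         nStarts = 1, maxIter = maxIter)
    grid$chisq[i] <- fit@chisq
  }
  grid
}

#' Fitted model curves for every profile of a dataset
#'
#' @param dataset the fitted \linkS4class{CestDataset}
#' @param result a \linkS4class{GlobalFitResult}
#' @return data.frame(residueId, B1_Hz, offset_Hz, observed, fitted, mask)
#' @export
fittedProfiles <- function(dataset, result) {
  sch <- schemeFromGlobals(result@model, result@globalPar)
  pops <- partitionPopulations(boundFraction(result@composition), sch)
  out <- list()
  for (p in dataset@profiles) {
    row <- result@residuePar[result@residuePar$residueId == p@residueId, ]
    if (nrow(row) == 0) next
    m <- simulateIntensities(spinFromRow(row[1, ]), sch, pops, p@experiment)
    out[[length(out) + 1]] <- data.frame(
      residueId = p@residueId, B1_Hz = p@experiment@B1,
      offset_Hz = p@offsets, observed = p@intensities, fitted = m,
      mask = p@mask)
  }
  do.call(rbind, out)
}
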