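# Staged orchestration of the full analysis, mirroring how the data would be
# analyzed interactively: noise -> masking -> residue-specific fits ->
# minor-state assignment -> global 3-site -> global 4-site (optionally with
# an anchoring-motif boundary search) -> model comparison -> bootstrap.

#' Run the staged CEST analysis pipeline
#'
#' @param dataset a \linkS4class{CestDataset}, or NULL to load from
#'   \code{config$paths$profile_table}
#' @param config optional list (or YAML path, see \code{\link{readRunConfig}})
#'   with sections constraint, experiment, model, bootstrap, paths
#' @param model final model, "4site" (default, with a 3-site stage first) or
#'   "3site" (stops after the global 3-site fit)
#' @param cribRange integer c(lo, hi): residues in this range form the
#'   anchoring-motif set; when \code{searchBoundaries = TRUE} the limits are
#'   optimized inside this range instead
#' @param searchBoundaries run \code{\link{searchCribBoundary}}
#' @param tieR2BC residues with the R2B = R2C tie in the global fits
#' @param excludedResidues residues excluded from all fits
#' @param bootstrapN bootstrap replicates (0 = skip)
#' @param seed RNG seed (start jitter, bootstrap)
#' @param nStartsResidue multi-start count of the residue-specific stage
#' @param maxIter iteration cap of the global fits
#' @param outDir if non-NULL, write summary JSON, residue parameter table and
#'   fitted-curve table here
#' @param verbose print per-stage progress
#' @return list with elements noise, residueFits, assignments, fit3, fit4,
#'   comparison, bootstrap, cribSearch, preferredModel, kon, timings, seed
#' @export
runCestPipeline <- function(dataset = NULL, config = NULL, model = "4site",
                            cribRange = NULL, searchBoundaries = FALSE,
                            tieR2BC = integer(), excludedResidues = integer(),
                            bootstrapN = 0, seed = 1, nStartsResidue = 3,
                            maxIter = 100, outDir = NULL, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
    if (verbose) message(sprintf("[%s] done (%.1f s)", stage, timings[[stage]]))
  }
  if (is.character(config)) config <- readRunConfig(config)
  if (!is.null(config)) {
    cc <- config$constraint
    if (is.null(dataset)) {
      comp <- MixtureComposition(cc$P0_uM, cc$R0_uM, cc$Kd_uM)
      ex <- config$experiment
      dataset <- readProfileTable(config$paths$profile_table, comp,
                                  Tsat = ex$Tsat %||% 0.4,
                                  larmor15N = ex$larmor15N %||% 96.3,
                                  carrier = ex$carrier %||% 118.5)
    }
    md <- config$model
    if (!is.null(md$model)) model <- md$model
    if (!is.null(md$crib_range)) cribRange <- md$crib_range
    if (!is.null(md$excluded_residues)) excludedResidues <- md$excluded_residues
    if (!is.null(md$tie_r2bc)) tieR2BC <- md$tie_r2bc
    if (!is.null(config$bootstrap$n)) bootstrapN <- config$bootstrap$n
    if (!is.null(config$bootstrap$seed)) seed <- config$bootstrap$seed
  }
  stopifnot(is(dataset, "CestDataset"))
  dataset@residueInfo$excluded <- dataset@residueInfo$excluded |
    dataset@residueInfo$residueId %in% excludedResidues

  # stage 1: per-profile noise (only where sigmas are absent) and exclusion
  # masks around the major-state dip
  dataset@profiles <- lapply(dataset@profiles, function(p) {
    if (all(p@sigmas <= 0)) p@sigmas <- rep(estimateNoise(p, useMask = FALSE),
                                            length(p@offsets))
    p@mask <- exclusionMask(p)
    p
  })
  noise <- vapply(dataset@profiles, function(p) p@sigmas[1], 0)
  tick("noise+mask")

  # stage 2: residue-specific 3-site fits
  info <- dataset@residueInfo
  fitIds <- info$residueId[!info$excluded]
  residueFits <- lapply(fitIds, function(rid)
    tryCatch(fitResidue3Site(dataset, rid, nStarts = nStartsResidue,
                             seed = seed + rid),
             error = function(e) NULL))
  names(residueFits) <- fitIds
  ok <- !vapply(residueFits, is.null, TRUE)
  tick("residue_fits")

  # stage 3: minor-state assignment where two dips are resolved
  assignments <- lapply(fitIds, function(rid)
    tryCatch(assignMinorStates(dataset, rid, nStarts = 1, seed = seed),
             error = function(e) NULL))
  names(assignments) <- fitIds
  tick("assignment")

  # stage 4: global 3-site fit, seeded from the residue-stage medians
  g3init <- c(
    koff = median(vapply(residueFits[ok], function(f) f@globalPar[["koff"]], 0)),
    kBC = median(vapply(residueFits[ok], function(f) f@globalPar[["kBC"]], 0)),
    kCB = median(vapply(residueFits[ok], function(f) f@globalPar[["kCB"]], 0)))
  ri3 <- do.call(rbind, lapply(residueFits[ok], resInitFromFit))
  spec3 <- FitSpec("3site", g3init, ri3, tieR2BC = tieR2BC)
  fit3 <- fitGlobal(dataset, spec3, maxIter = maxIter)
  ref3 <- refineResidueFits(dataset, spec3, fit3)
  if (length(ref3$refined)) {
    spec3 <- FitSpec("3site", fit3@globalPar[names(g3init)], ref3$residueInit,
                     tieR2BC = tieR2BC)
    fit3 <- fitGlobal(dataset, spec3, maxIter = maxIter)
  }
  tick("global_3site")

  fit4 <- NULL; comparison <- NULL; cribSearch <- NULL; boot <- NULL
  if (model == "4site") {
    # stage 5: global 4-site fit; dwFA initialized to dwFB inside the
    # anchoring motif and 0 outside, koff/kexBC carried over from 3-site
    cribSet <- if (is.null(cribRange)) integer()
               else fitIds[fitIds >= cribRange[1] & fitIds <= cribRange[2]]
    ri4 <- resInitFromFit(fit3)
    ri4$dwFA <- ifelse(ri4$residueId %in% cribSet, ri4$dwFB, 0)
    # a non-motif residue whose 3-site intermediate collapsed onto the free
    # state was fitting the anchored state A (at 0 in the 4-site model);
    # restart its true intermediate at the bound position
    remap <- !(ri4$residueId %in% cribSet) &
      abs(ri4$dwFB) < 0.3 & abs(ri4$dwFC) > 1
    ri4$dwFB[remap] <- ri4$dwFC[remap]
    g3 <- fit3@globalPar
    g4init <- c(koff = unname(g3[["koff"]]), kexAB = 150,
                kexBC = unname(g3[["kBC"]] + g3[["kCB"]]),
                KeqAB = 1, KeqBC = unname(g3[["kBC"]] / g3[["kCB"]]))
    spec4 <- FitSpec("4site", g4init, ri4, cribSet = cribSet,
                     tieR2BC = tieR2BC)
    if (searchBoundaries && !is.null(cribRange)) {
      cribSearch <- searchCribBoundary(dataset, spec4, cribRange,
                                      maxIter = max(30, maxIter %/% 2))
      spec4 <- FitSpec("4site", g4init, ri4, cribSet = cribSearch$cribSet,
                       tieR2BC = tieR2BC)
      tick("crib_search")
    }
    fit4 <- fitGlobalStaged(dataset, spec4, maxIter = maxIter)
    # residue-level local minima (merged or aliased dips) are escaped by
    # re-scanning misfit residues with the globals fixed, then refitting
    for (round in 1:2) {
      ref4 <- refineResidueFits(dataset, spec4, fit4)
      if (length(ref4$refined) == 0) break
      spec4 <- FitSpec("4site", fit4@globalPar[names(g4init)],
                       ref4$residueInit, cribSet = spec4@cribSet,
                       tieR2BC = tieR2BC)
      fit4 <- fitGlobal(dataset, spec4, maxIter = maxIter)
    }
    tick("global_4site")
    comparison <- compareModels(fit3, fit4)
    if (bootstrapN > 0) {
      boot <- bootstrapGlobal(dataset, spec4, fit4, n = bootstrapN, seed = seed)
      tick("bootstrap")
    }
  }
  finalFit <- if (!is.null(fit4) &&
                  (is.null(comparison) || comparison$decision == "4site"))
                fit4 else fit3
  out <- list(noise = noise, residueFits = residueFits,
              assignments = assignments, fit3 = fit3, fit4 = fit4,
              comparison = comparison, cribSearch = cribSearch,
              bootstrap = boot,
              preferredModel = if (is.null(comparison)) "3site"
                               else comparison$decision,
              kon = tryCatch(deriveKon(finalFit), error = function(e) NA_real_),
              timings = timings, seed = seed, dataset = dataset)
  if (!is.null(outDir)) writeCestBundle(out, outDir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeCestBundle <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  finalFit <- if (identical(result$preferredModel, "4site")) result$fit4 else result$fit3
  summary <- list(
    seed = result$seed,
    preferred_model = result$preferredModel,
    comparison = result$comparison[c("F", "p", "decision")],
    global = as.list(finalFit@globalPar),
    global_se = as.list(finalFit@globalSE),
    kon_M_s = result$kon,
    chisq = finalFit@chisq, n_points = finalFit@nPoints,
    n_par = finalFit@nPar,
    bootstrap_ci68 = if (!is.null(result$bootstrap))
      as.list(as.data.frame(result$bootstrap@ci68)) else NULL,
    timings_s = as.list(result$timings))
  jsonlite::write_json(summary, file.path(outDir, "cest_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(finalFit@residuePar, file.path(outDir, "residue_parameters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fittedProfiles(result$dataset, finalFit),
              file.path(outDir, "fitted_profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outDir)
}

#' Run the ITC thermodynamics pipeline
#'
#' Per-temperature one-set-of-sites fits (duplicates averaged per
#' temperature), assembly of the thermodynamic table, heat-capacity and
#' iso-entropic-temperature regression, Kd extrapolation to a reference
#' temperature, and the Spolar-Record decomposition with the folded-residue
#' estimate.
#'
#' @param series list of \linkS4class{InjectionSeries} covering >= 3
#'   temperatures, or NULL to read \code{config$paths$injection_table}
#' @param config optional list or YAML path
#' @param Textrapolate temperature (K) for the Kd extrapolation
#' @param Tdecompose temperature (K) at which to evaluate the decomposition
#' @param perResidue per-residue conformational entropy loss (J mol-1 K-1)
#' @param outDir optional output directory for JSON + tables
#' @return list with fits, thermo (\linkS4class{ThermoTable}), dCp, TS,
#'   KdExtrapolated, decomposition (\linkS4class{EntropyDecomposition})
#' @export
runThermoPipeline <- function(series = NULL, config = NULL,
                              Textrapolate = 298.15, Tdecompose = 298.15,
                              perResidue = -24, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(series)) {
    if (is.null(config$paths$injection_table))
      stop("no injection series and no injection_table in config")
    series <- readInjectionTable(config$paths$injection_table)
  }
  temps <- vapply(series, function(s) s@temperature, 0)
  if (length(unique(temps)) < 3)
    stop("need injection series at >= 3 temperatures (got ",
         length(unique(temps)), ")")
  fits <- lapply(series, fitOneSite)
  perT <- data.frame(T_K = temps,
                     Kd = vapply(fits, function(f) f@Kd, 0),
                     dH = vapply(fits, function(f) f@dH, 0))
  agg <- do.call(rbind, lapply(split(perT, perT$T_K), function(sub)
    data.frame(T_K = sub$T_K[1], Kd = mean(sub$Kd), dH = mean(sub$dH))))
  thermo <- ThermoTable(agg$T_K, agg$Kd, agg$dH)
  dCp <- heatCapacity(thermo)
  TS <- isoEntropicTemp(thermo)
  KdX <- extrapolateKd(thermo, Textrapolate)
  dec <- spolarRecord(dCp, TS, T = Tdecompose, perResidue = perResidue)
  out <- list(fits = fits, thermo = thermo, dCp = dCp, TS = TS,
              KdExtrapolated = KdX, Textrapolate = Textrapolate,
              decomposition = dec,
              totalEntropyAtTS = spolarRecord(dCp, TS, T = TS)@dSTotal)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(
      dCp_kJ_mol_K = dCp, T_S_K = TS,
      Kd_extrapolated_uM = KdX, T_extrapolate_K = Textrapolate,
      dS_conf_J_mol_K = dec@dSConf, dS_desolv_J_mol_K = dec@dSDesolv,
      dS_rt_J_mol_K = dec@dSrt, folded_residues = dec@foldedResidues,
      total_entropy_at_TS_check = abs(out$totalEntropyAtTS) < 1e-9),
      file.path(outDir, "thermo_summary.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    write.table(thermoData(thermo), file.path(outDir, "thermo_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
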