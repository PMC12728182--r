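# Staged CEST inference: noise estimation, dip picking, residue fits,
# assignment, model comparison, bootstrap mechanics, grid search.

test_that("second-difference noise estimator is calibrated", {
  set.seed(3)
  e <- CestExperiment(B1 = 20, Tsat = 0.4, irradiation = "cw",
                      offsets = seq_len(100) * 8 - 400)
  mk <- function(y) new("CestProfile", residueId = 1L, experiment = e,
                        offsets = e@offsets, intensities = y,
                        sigmas = rep(0, 100), mask = rep(TRUE, 100))
  # pure Gaussian noise, sigma 0.01: seeded single estimate and the
  # replicate mean both sit near the truth
  expect_true(abs(estimateNoise(mk(rnorm(100, 0.8, 0.01))) - 0.01) < 0.002)
  sig <- replicate(20, estimateNoise(mk(rnorm(100, 0.8, 0.01))))
  expect_equal(mean(sig), 0.01, tolerance = 0.05)
  expect_true(all(sig > 0.007 & sig < 0.013))
  # a straight line is annihilated by the second difference
  expect_equal(estimateNoise(mk(seq(0, 1, length.out = 100))), 0,
               tolerance = 1e-12)
  # smooth Lorentzian dip: curvature leaks far less than real noise
  lor <- 1 - 0.5 / (1 + ((e@offsets - 30) / 40)^2)
  expect_lt(estimateNoise(mk(lor)), 0.1 * 0.5 / sqrt(6))
  noisy <- estimateNoise(mk(lor + rnorm(100, 0, 0.01)))
  expect_lt(estimateNoise(mk(lor)), 0.3 * noisy)
  expect_error(estimateNoise(mk(rep(1, 100))[c(1, 2)]))
})

test_that("dip picking finds separated minima and rejects flat noise", {
  sch <- paperScheme(); comp <- paperComp()
  spin <- testSpin(shiftF = 117, dwFA = 0, dwFB = -3, dwFC = 5,
                   R2B = 18, R2C = 18)
  e <- CestExperiment(B1 = 20.5, Tsat = 0.4, irradiation = "cw",
                      offsets = seq(-800, 800, 10), carrier = 118.5)
  p <- simulateProfile(spin, sch, comp, e, sigma = 1e-4)
  dips <- pickDips(p, threshold = 10, sigma = 1e-3, majorShift = 117)
  # major dip excluded; the two minor states recovered at their shifts
  expect_gte(nrow(dips), 2)
  got <- sort(dips$dwPpm[1:2])
  expect_equal(got, c(-3, 5), tolerance = 0.11 / 3)
  # flat noise-only profile yields no candidates at 5 sigma
  set.seed(9)
  pn <- new("CestProfile", residueId = 1L, experiment = e,
            offsets = e@offsets, intensities = rnorm(161, 0.7, 0.004),
            sigmas = rep(0.004, 161), mask = rep(TRUE, 161))
  expect_identical(nrow(pickDips(pn, threshold = 5, sigma = 0.004,
                                 majorShift = 117)), 0L)
})

test_that("slow-exchange shift differences come from major-minor dip spacing", {
  # 2-state profile with dw = 3.00 ppm: dip difference reads the shift
  sch <- ExchangeScheme("4site", kon = 7.3e5, koff = 56, kAB = 0, kBA = 10,
                        kBC = 89, kCB = 94)
  spin <- testSpin(shiftF = 116, dwFA = 3, dwFB = 1, dwFC = 1, R2A = 20)
  e <- CestExperiment(B1 = 20.5, Tsat = 0.4, irradiation = "cw",
                      offsets = seq(-600, 600, 8), carrier = 118.5)
  p <- simulateProfile(spin, sch, paperComp(), e)
  dips <- pickDips(p, threshold = 10, sigma = 1e-3, majorShift = 116)
  expect_equal(dips$dwPpm[1], 3.00, tolerance = 8 / 96.3 / 3)
})

test_that("alias deconvolution recovers shifts beyond the DANTE window", {
  sch <- paperScheme(); comp <- paperComp()
  spin <- testSpin(shiftF = 112, dwFA = 0, dwFB = 2.5, dwFC = 5.5,
                   R2B = 20, R2C = 20)
  prof <- lapply(defaultExperiments(), function(e)
    simulateProfile(spin, sch, comp, e, sigma = 1e-4))
  cands <- dipCandidates(prof, 112, threshold = 5)
  # the deep fully-bound dip aliases consistently across windows
  top <- cands[cands$support >= 2, ]
  expect_true(any(abs(top$dwPpm - 5.5) < 0.15))
  # the exchange-broadened intermediate dip is weaker and may surface in a
  # single window only, but its deconvolved position is on the candidate list
  expect_true(any(abs(cands$dwPpm - 2.5) < 0.15))
})

test_that("residue-specific 3-site fit recovers noiseless parameters", {
  sch3 <- ExchangeScheme("3site", kon = 7.3e5, koff = 56, kBC = 89, kCB = 94)
  comp <- paperComp()
  spin <- testSpin(residueId = 340L, shiftF = 114, dwFA = NA, dwFB = -2.2,
                   dwFC = 3.1, R1F = 1.4, R2F = 6, R2B = 22, R2C = 22)
  prof <- lapply(tinyExperiments(), function(e)
    simulateProfile(spin, sch3, comp, e, sigma = 0))
  ds <- CestDataset(prof, comp)
  fit <- fitResidue3Site(ds, 340L, nStarts = 3, seed = 2)
  expect_true(fit@converged)
  g <- fit@globalPar
  expect_equal(unname(g[["koff"]]), 56, tolerance = 0.01)
  expect_equal(unname(g[["kBC"]]), 89, tolerance = 0.01)
  expect_equal(unname(g[["kCB"]]), 94, tolerance = 0.01)
  expect_equal(fit@residuePar$dwFB, -2.2, tolerance = 0.01)
  expect_equal(fit@residuePar$dwFC, 3.1, tolerance = 0.01)
  # population-sum constraint holds by construction, not by fitting
  sch <- cestfold:::schemeFromGlobals("3site", g)
  p <- populations(partitionPopulations(boundFraction(comp), sch))
  expect_equal(p[["B"]] + p[["C"]], boundFraction(comp), tolerance = 1e-12)
})

test_that("minor-state assignment prefers the true labeling via the swap test", {
  set.seed(5)
  sch3 <- ExchangeScheme("3site", kon = 7.3e5, koff = 56, kBC = 140, kCB = 70)
  comp <- paperComp()  # K_eq,BC = 2 so p_B < p_C
  spin <- testSpin(residueId = 351L, shiftF = 114, dwFA = NA, dwFB = -2.0,
                   dwFC = 3.5, R1F = 1.4, R2F = 6, R2B = 14, R2C = 30)
  prof <- lapply(tinyExperiments(), function(e)
    simulateProfile(spin, sch3, comp, e, sigma = 0.003))
  prof <- lapply(prof, function(p) {
    p@intensities <- p@intensities + rnorm(length(p@offsets), 0, 0.003); p })
  ds <- CestDataset(prof, comp)
  res <- assignMinorStates(ds, 351L, dwB = -2.0, dwC = 3.5, shiftF = 114,
                           nStarts = 2, seed = 3)
  expect_false(res$ambiguous)
  expect_identical(res$accepted, "original")
  expect_true(res$fitSwapped@chisq >= res$fit@chisq || res$reverted)
  expect_lt(res$pB, res$pC)
  # degenerate dips are flagged, not force-assigned
  amb <- assignMinorStates(ds, 351L, dwB = 2, dwC = -2, shiftF = 114)
  expect_true(amb$ambiguous)
})

test_that("model comparison follows the nested F-test", {
  mk <- function(chisq, nPar) {
    new("GlobalFitResult", model = "3site", globalPar = c(koff = 1),
        globalSE = c(koff = NA_real_), residuePar = data.frame(),
        chisq = chisq, nPoints = 500L, nPar = as.integer(nPar),
        residuals = list(), converged = TRUE,
        composition = paperComp())
  }
  # identical fits: F = 0, p = 1
  cmp0 <- compareModels(mk(400, 20), mk(400, 25))
  expect_identical(cmp0$F, 0); expect_identical(cmp0$p, 1)
  expect_identical(cmp0$decision, "3site")
  # large improvement for 5 extra parameters: decisive for the larger model
  cmp1 <- compareModels(mk(900, 20), mk(450, 25))
  expect_identical(cmp1$decision, "4site")
  expect_lt(cmp1$p, 1e-6)
  expect_equal(cmp1$F, ((900 - 450) / 5) / (450 / 475), tolerance = 1e-12)
  # worse larger model: decision reverts with p = 1
  cmp2 <- compareModels(mk(400, 20), mk(410, 25))
  expect_identical(cmp2$decision, "3site")
  expect_identical(cmp2$p, 1)
})

test_that("masked points never contribute to the fit objective", {
  sch3 <- ExchangeScheme("3site", kon = 7.3e5, koff = 56, kBC = 89, kCB = 94)
  comp <- paperComp()
  spin <- testSpin(residueId = 7L, dwFA = NA, dwFB = 1.5, dwFC = 2.5)
  e <- tinyExperiments()[[2]]
  p <- simulateProfile(spin, sch3, comp, e, sigma = 0.004)
  p@mask <- exclusionMask(p)
  ri <- data.frame(residueId = 7L, shiftF = 118, dwFA = NA, dwFB = 1.5,
                   dwFC = 2.5, R1F = 1.3, R2F = 5, R2B = 25, R2C = 25)
  spec <- FitSpec("3site", c(koff = 56, kBC = 89, kCB = 94), ri,
                  fitShiftF = FALSE)
  chiAt <- function(prof) {
    codec <- cestfold:::makeCodec(CestDataset(list(prof), comp), spec)
    sum(cestfold:::codecResiduals(cestfold:::codecPack(codec), codec)^2)
  }
  c1 <- chiAt(p)
  p2 <- p
  p2@intensities[!p2@mask] <- p2@intensities[!p2@mask] + 5
  expect_equal(chiAt(p2), c1, tolerance = 1e-12)
})

test_that("bootstrap resampling preserves profile sizes and handles n = 0", {
  sc <- tinyScenario(seed = 2)
  gen <- generateCestDataset(sc)
  ds <- gen$dataset
  set.seed(1)
  for (p in ds@profiles[1:3]) {
    r <- cestfold:::resampleProfile(p)
    expect_identical(length(r@offsets), length(p@offsets))
    expect_identical(r@offsets, p@offsets)
    # multiplicity-weighted representation: weights sum to the profile size
    expect_equal(sum((p@sigmas / r@sigmas)^2 * (r@mask | !p@mask) *
                       ifelse(r@mask, 1, 0)),
                 length(p@offsets), tolerance = 1e-9)
  }
  ri <- data.frame(residueId = 325L, shiftF = 118, dwFA = 1, dwFB = 1,
                   dwFC = 1.2, R1F = 1.3, R2F = 5, R2B = 25, R2C = 25)
  spec <- FitSpec("4site", paperGlobals(), ri)
  pt <- new("GlobalFitResult", model = "4site", globalPar = paperGlobals(),
            globalSE = paperGlobals() * NA, residuePar = ri, chisq = 1,
            nPoints = 100L, nPar = 10L, residuals = list(), converged = TRUE,
            composition = paperComp())
  b0 <- bootstrapGlobal(ds, spec, pt, n = 0, seed = 1)
  expect_identical(b0@nReplicates, 0L)
  expect_identical(b0@pointEstimate, paperGlobals())
})

test_that("profile-likelihood grid search brackets the free optimum", {
  set.seed(11)
  sc <- tinyScenario(seed = 3, sigma = 0.002,
                     experiments = tinyExperiments(cwStep = 200))
  gen <- generateCestDataset(sc)
  ds <- gen$dataset
  ds@profiles <- lapply(ds@profiles, function(p) { p@mask <- exclusionMask(p); p })
  ri <- sc@roster[, c("residueId", "shiftF", "dwFA", "dwFB", "dwFC", "R1F",
                      "R2F", "R2B", "R2C")]
  spec <- FitSpec("4site", paperGlobals(), ri,
                  cribSet = sc@roster$residueId[sc@roster$class == "crib"],
                  fitShiftF = FALSE)
  free <- fitGlobal(ds, spec, maxIter = 60)
  grid <- gridSearch(ds, spec, kexABGrid = c(100, 136, 180),
                     kexBCGrid = c(140, 183, 240), maxIter = 40)
  expect_true(all(grid$chisq >= free@chisq - 1e-6))
  best <- grid[which.min(grid$chisq), ]
  expect_equal(best$kexAB, 136); expect_equal(best$kexBC, 183)
})
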