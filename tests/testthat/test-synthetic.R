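# Synthetic-data generation: determinism, class structure, noise statistics,
# thermodynamic propagation.

test_that("scenarios are deterministic and carry the class shift rules", {
  s1 <- makeDefaultScenario(seed = 4)
  s2 <- makeDefaultScenario(seed = 4)
  expect_identical(s1@roster, s2@roster)
  r <- s1@roster
  # anchoring motif truth used by the boundary search
  expect_true(all(c(325L, 327L, 330L, 331L, 333L) %in%
                    r$residueId[r$class == "crib"]))
  crib <- r[r$class == "crib", ]
  expect_equal(crib$dwFA, crib$dwFB, tolerance = 1e-12)
  expect_true(all(abs(crib$dwFA) >= 1 & abs(crib$dwFA) <= 4))
  m1 <- r[r$class == "mre1_helix", ]
  expect_true(all(m1$dwFA == 0))
  expect_true(all(abs(m1$dwFB) >= 1 & abs(m1$dwFB) <= 5))
  m2 <- r[r$class == "mre2", ]
  expect_true(all(m2$dwFA == 0))
  # partially shifted intermediate: strictly between free and bound
  expect_true(all(abs(m2$dwFB) > 0 & abs(m2$dwFB) < abs(m2$dwFC)))
  expect_true(all(sign(m2$dwFB) == sign(m2$dwFC)))
})

test_that("generated datasets are reproducible with full profile coverage", {
  sc <- tinyScenario(seed = 6)
  g1 <- generateCestDataset(sc)
  g2 <- generateCestDataset(sc)
  expect_equal(length(g1$dataset@profiles),
               nrow(sc@roster) * length(sc@experiments))
  expect_identical(
    lapply(g1$dataset@profiles, function(p) p@intensities),
    lapply(g2$dataset@profiles, function(p) p@intensities))
})

test_that("generator noise is homoscedastic Gaussian", {
  # residuals against the clean forward curves across several small
  # scenarios: approximately normal with the nominal sigma
  res <- unlist(lapply(1:4, function(s) {
    sc <- makeDefaultScenario(seed = s, sigma = 0.004)
    scClean <- makeDefaultScenario(seed = s, sigma = 0)
    g <- generateCestDataset(sc)
    g0 <- generateCestDataset(scClean)
    unlist(Map(function(a, b) a@intensities - b@intensities,
               g$dataset@profiles, g0$dataset@profiles))
  }))
  expect_gte(length(res), 5000)
  expect_equal(sd(res), 0.004, tolerance = 0.05)
  sk <- mean((res - mean(res))^3) / sd(res)^3
  expect_lt(abs(sk), 0.3)
})

test_that("noiseless synthetic data refit at truth has vanishing residuals", {
  sc <- tinyScenario(seed = 12, sigma = 0)
  gen <- generateCestDataset(sc)
  ri <- sc@roster[, c("residueId", "shiftF", "dwFA", "dwFB", "dwFC", "R1F",
                      "R2F", "R2B", "R2C")]
  spec <- FitSpec("4site", paperGlobals(), ri,
                  cribSet = sc@roster$residueId[sc@roster$class == "crib"],
                  fitShiftF = FALSE)
  codec <- cestfold:::makeCodec(gen$dataset, spec)
  chi <- sum(cestfold:::codecResiduals(cestfold:::codecPack(codec), codec)^2)
  expect_lt(chi, 1e-6)
})

test_that("synthetic decays match the printed schedule and recover exactly", {
  dc <- generateDecays(c(`330` = 6, `331` = 12), sigma = 0, seed = 2)
  expect_length(dc, 2L)
  expect_length(dc[[1]]@delays, 11L)
  expect_equal(fitExponential(dc[[1]])@rate, 6, tolerance = 1e-8)
  expect_equal(fitExponential(dc[[2]])@rate, 12, tolerance = 1e-8)
  d2 <- generateDecays(c(`330` = 6, `331` = 12), sigma = 0.5, seed = 2)
  d3 <- generateDecays(c(`330` = 6, `331` = 12), sigma = 0.5, seed = 2)
  expect_identical(d2[[1]]@intensities, d3[[1]]@intensities)
})

test_that("synthetic titrations propagate the anchor thermodynamics", {
  gt <- generateTitrations(sigmaQ = 0, seed = 5)
  # negative dCp with dH(25C) = 0: binding weakens toward low temperature
  expect_gt(gt$truth$Kd_uM[gt$truth$T_K == 278.15], 24)
  expect_gt(gt$truth$Kd_uM[gt$truth$T_K == 308.15], 24)
  expect_gt(gt$truth$Kd_uM[1], gt$truth$Kd_uM[4])
  # noiseless series refit recovers the generating parameters to 0.1%
  f <- fitOneSite(gt$series[[2]])
  expect_equal(f@Kd, gt$truth$Kd_uM[2], tolerance = 1e-3)
  expect_equal(f@dH, gt$truth$dH_kJ[2], tolerance = 1e-3)
  expect_equal(f@n, 1, tolerance = 1e-3)
  # duplicates give independent noisy series
  gt2 <- generateTitrations(sigmaQ = 1, duplicates = 2, seed = 5)
  expect_length(gt2$series, 8L)
  expect_false(identical(gt2$series[[1]]@heats, gt2$series[[2]]@heats))
})
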