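# ITC one-set-of-sites model, temperature-series thermodynamics and the
# Spolar-Record entropy decomposition.

paperSeries <- function(Kd = 24, dH = -30, n = 1, qOffset = 0, T = 298.15) {
  s <- InjectionSeries(temperature = T, cellVolume = 200, cellConc = 125,
                       syringeConc = 1000, volumes = rep(3, 39),
                       heats = numeric(39),
                       segments = rep(1:3, each = 13))
  s@heats <- oneSiteHeats(c(n = n, Kd = Kd, dH = dH, qOffset = qOffset), s)
  s
}

test_that("one-site heats: offset-only, saturation and the Wiseman number", {
  s0 <- paperSeries(dH = 0, qOffset = 2.5)
  expect_equal(oneSiteHeats(c(n = 1, Kd = 24, dH = 0, qOffset = 2.5), s0),
               rep(2.5, 39), tolerance = 1e-12)
  # saturating titration: late heats approach the offset
  s <- paperSeries(Kd = 1, dH = -40, qOffset = 1)
  q <- s@heats
  expect_lt(abs(q[39] - 1), 0.01 * abs(q[1]))
  # c-parameter of the study design
  expect_equal(wisemanC(1, 125, 24), 125 / 24, tolerance = 1e-12)
  expect_error(oneSiteHeats(c(n = 1, Kd = 24, dH = -30, qOffset = 0),
                            InjectionSeries(298.15, 200, 125, 0,
                                            rep(3, 12), numeric(12))))
})

test_that("one-site fit recovers noiseless parameters to 0.1%", {
  s <- paperSeries(Kd = 24, dH = -30, n = 1)
  f <- fitOneSite(s)
  expect_true(f@converged)
  expect_equal(f@n, 1, tolerance = 1e-3)
  expect_equal(f@Kd, 24, tolerance = 1e-3)
  expect_equal(f@dH, -30, tolerance = 1e-3)
  # all-zero heats: unidentifiable, flagged
  sz <- paperSeries(dH = 0)
  expect_true(fitOneSite(sz)@flagged)
  expect_error(fitOneSite(InjectionSeries(298.15, 200, 125, 1000,
                                          rep(3, 5), numeric(5))),
               "injections")
})

test_that("noisy one-site fits recover Kd within 15%", {
  set.seed(17)
  s <- paperSeries(Kd = 24, dH = -30)
  s@heats <- s@heats + rnorm(39, 0, 1)
  f <- fitOneSite(s)
  expect_lt(abs(f@Kd / 24 - 1), 0.15)
  expect_lt(abs(f@dH / -30 - 1), 0.05)
})

test_that("Gibbs free energy follows the 1 M standard state", {
  expect_equal(gibbs(24, 298.15), -26.37, tolerance = 0.01 / 26)
  expect_equal(gibbs(1e6, 310), 0, tolerance = 1e-12)
  expect_true(all(diff(gibbs(c(1, 10, 100, 1000), 298.15)) > 0))
  expect_error(gibbs(-1, 298.15), "Kd")
})

test_that("thermo table identities hold row-wise", {
  tab <- ThermoTable(c(278.15, 288.15, 298.15), c(46, 30, 24),
                     c(56, 28, 0))
  td <- thermoData(tab)
  expect_equal(td$dG_kJ, td$dH_kJ - td$T_K * td$dS_J / 1000,
               tolerance = 1e-12)
  expect_equal(td$dG_kJ, 8.314 * td$T_K * log(td$Kd_uM * 1e-6) / 1000,
               tolerance = 1e-12)
})

test_that("heat capacity is the dH-vs-T slope", {
  T <- c(278.15, 283.15, 288.15, 308.15)
  tab <- ThermoTable(T, rep(24, 4), -2.8 * (T - 298.15))
  expect_equal(heatCapacity(tab), -2.8, tolerance = 1e-10)
  tabC <- ThermoTable(T, rep(24, 4), rep(10, 4))
  expect_equal(heatCapacity(tabC), 0, tolerance = 1e-10)
  expect_error(heatCapacity(ThermoTable(298.15, 24, 0)), "temperatures")
  # noisy regression stays within 10%
  set.seed(30)
  dH <- -2.8 * (rep(T, 2) - 298.15) + rnorm(8, 0, 1)
  tabN <- ThermoTable(rep(T, 2), rep(24, 8), dH)
  expect_lt(abs(heatCapacity(tabN) / -2.8 - 1), 0.10)
})

test_that("Kd extrapolation is exact for linear dG and matches the oracle", {
  # exactly linear dG(T): interpolation returns the constructed value
  T <- c(278.15, 288.15, 308.15)
  dG <- -26 + 0.1 * (T - 298.15)
  Kd <- exp(dG * 1000 / (8.314 * T)) * 1e6
  tab <- ThermoTable(T, Kd, dG)   # dH := dG makes dS = 0 rows; fine here
  expect_equal(gibbs(extrapolateKd(tab, 298.15), 298.15), -26,
               tolerance = 1e-9)
  expect_error(extrapolateKd(ThermoTable(298.15, 24, 0), 298.15))
  # curved-truth oracle: propagate Kd(25C) = 24 uM, dH(25C) = 0,
  # dCp = -2.8 and regress the four study temperatures; the linear
  # extrapolation inherits a curvature offset that the oracle quantifies
  tr <- propagateThermo(c(278.15, 283.15, 288.15, 308.15), 24, 0, -2.8)
  tab2 <- ThermoTable(tr$T_K, tr$Kd_uM, tr$dH_kJ)
  oracleFit <- lm(dG_kJ ~ T_K, thermoData(tab2))
  oracleKd <- exp(unname(predict(oracleFit,
                                 data.frame(T_K = 298.15))) * 1000 /
                    (8.314 * 298.15)) * 1e6
  expect_equal(extrapolateKd(tab2, 298.15), oracleKd, tolerance = 1e-9)
})

test_that("iso-entropic temperature is the dS zero crossing", {
  T <- c(280, 290, 300, 310)
  # constructed crossing at 307.1 K
  dS <- 2.5 * (T - 307.1)
  tab <- ThermoTable(T, rep(24, 4), gibbs(24, T) + T * dS / 1000)
  expect_equal(isoEntropicTemp(tab), 307.1, tolerance = 1e-9)
  # thermodynamic propagation from the printed anchor crosses near 307-308
  tr <- propagateThermo(c(278.15, 283.15, 288.15, 308.15), 24, 0, -2.8)
  tab2 <- ThermoTable(tr$T_K, tr$Kd_uM, tr$dH_kJ)
  TS <- isoEntropicTemp(tab2)
  expect_gt(TS, 306); expect_lt(TS, 309)
  # constant dS: undefined
  tabC <- ThermoTable(T, rep(24, 4), gibbs(24, T) + T * 0.05)
  expect_warning(TSc <- isoEntropicTemp(tabC), "undefined")
  expect_true(is.na(TSc))
})

test_that("Spolar-Record decomposition and folded-residue estimate", {
  d <- spolarRecord(-2.8, 307.1)
  expect_equal(d@dSConf, -952.8, tolerance = 0.1 / 952)
  expect_equal(d@foldedResidues, 40)
  # vanishing dCp leaves only the constant offset
  expect_equal(spolarRecord(0, 307.1)@dSConf, 110, tolerance = 1e-12)
  # total entropy vanishes at the iso-entropic temperature by construction
  set.seed(31)
  for (i in 1:10) {
    dCp <- runif(1, -5, -0.5); TS <- runif(1, 280, 340)
    expect_lt(abs(spolarRecord(dCp, TS, T = TS)@dSTotal), 1e-9)
  }
  expect_equal(foldedResidueCount(-952.8, -24), 40)
  expect_equal(foldedResidueCount(0, -24), 0)
  expect_equal(foldedResidueCount(-24, -24), 1)
  expect_error(foldedResidueCount(-100, 24), "negative")
  # unit-safety guard on the 1000x conversion: the kJ input reproduces the
  # same decomposition as the explicit J evaluation
  dJ <- -1.66 * (-2800) * log(307.1 / 386) + 110
  expect_equal(spolarRecord(-2.8, 307.1)@dSConf, dJ, tolerance = 1e-12)
})
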