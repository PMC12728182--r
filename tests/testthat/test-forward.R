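# Bloch-McConnell forward simulation: generator structure, propagation
# against an ODE oracle, CW and DANTE saturation, profile features, masks.

test_that("generator has conservative exchange blocks and stable spectrum", {
  sch <- paperScheme(); comp <- paperComp()
  pops <- partitionPopulations(boundFraction(comp), sch)
  expt <- cwExperiment()
  G <- bmGenerator(testSpin(), sch, pops, expt, offset = 50)
  expect_equal(dim(G), c(12L, 12L))
  # exchange part conserves magnetization per Cartesian component: columns
  # of (G - relaxation/precession diagonal blocks) sum to zero; equivalently
  # colSums(G) equals the per-state relaxation column sums
  K <- cestfold:::rateMatrixFromPops(sch, pops)
  expect_equal(colSums(K), setNames(rep(0, 4), stateLabels(sch)),
               tolerance = 1e-14)
  expect_true(all(Re(eigen(G)$values) <= 1e-10))
  # no saturation, no exchange: block-diagonal relaxation + precession
  sch0 <- ExchangeScheme("4site", kon = 0, koff = 1e-12, kAB = 1e-12,
                         kBA = 1e-12, kBC = 1e-12, kCB = 1e-12)
  pops0 <- partitionPopulations(0, sch0)
  G0 <- bmGenerator(testSpin(), sch0, pops0, expt, offset = 50, B1 = 0)
  offblock <- G0
  for (i in 0:3) offblock[3 * i + 1:3, 3 * i + 1:3] <- 0
  expect_lt(max(abs(offblock)), 1e-10)
})

test_that("matrix-exponential propagation agrees with the ODE oracle", {
  set.seed(7)
  for (i in 1:20) {
    inst <- randomInstance()
    pops <- partitionPopulations(boundFraction(inst$comp), inst$scheme)
    G <- bmGenerator(inst$spin, inst$scheme, pops, inst$expt, inst$offset)
    M0 <- numeric(12); M0[3 * (1:4)] <- populations(pops)
    Mexp <- propagateCW(G, M0, 0.4)
    Mode <- odePropagate(G, M0, 0.4)
    expect_lt(max(abs(Mexp - Mode)), 1e-8)
  }
})

test_that("CW propagation handles the identity and error cases", {
  sch <- paperScheme(); comp <- paperComp()
  pops <- partitionPopulations(boundFraction(comp), sch)
  G <- bmGenerator(testSpin(), sch, pops, cwExperiment(), offset = 0)
  M0 <- numeric(12); M0[3 * (1:4)] <- populations(pops)
  expect_identical(propagateCW(G, M0, 0), M0)
  expect_error(propagateCW(G, M0, -1), "Tsat")
  expect_error(propagateCW(G, M0[1:9], 0.4), "dimension")
})

test_that("far-off-resonance baseline decays at R1F without exchange", {
  sch0 <- ExchangeScheme("4site", kon = 0, koff = 1e-12, kAB = 1e-12,
                         kBA = 1e-12, kBC = 1e-12, kCB = 1e-12)
  comp0 <- MixtureComposition(500, 0, 24)
  e <- CestExperiment(B1 = 20, Tsat = 0.4, irradiation = "cw",
                      offsets = c(1e5, 2e5))
  p <- simulateProfile(testSpin(), sch0, comp0, e)
  expect_equal(p@intensities, rep(exp(-1.3 * 0.4), 2), tolerance = 1e-3)
})

test_that("profiles normalize to 1 at zero saturation time", {
  e0 <- CestExperiment(B1 = 20, Tsat = 0, irradiation = "cw",
                       offsets = seq(-200, 200, 50))
  p <- simulateProfile(testSpin(), paperScheme(), paperComp(), e0)
  expect_equal(p@intensities, rep(1, length(e0@offsets)), tolerance = 1e-12)
})

test_that("DANTE saturation reduces to CW in the principal band", {
  spin <- testSpin(shiftF = 118.6, dwFA = 0.4, dwFB = 0.5, dwFC = 0.6)
  offs <- seq(-100, 100, 10)
  for (b1 in c(5.2, 10.3, 20.5)) {
    eD <- CestExperiment(B1 = b1, Tsat = 0.4, irradiation = "dante",
                         danteWindow = 800, offsets = offs)
    eC <- CestExperiment(B1 = b1, Tsat = 0.4, irradiation = "cw",
                         offsets = offs)
    d <- simulateProfile(spin, paperScheme(), paperComp(), eD)@intensities
    cw <- simulateProfile(spin, paperScheme(), paperComp(), eC)@intensities
    expect_lt(max(abs(d - cw)), 0.02)
  }
})

test_that("DANTE profiles are periodic in the offset with the window", {
  e <- CestExperiment(B1 = 10, Tsat = 0.4, irradiation = "dante",
                      danteWindow = 400, offsets = c(-50, 350))
  p <- simulateProfile(testSpin(), paperScheme(), paperComp(), e)
  expect_lt(abs(diff(p@intensities)), 1e-6)
})

test_that("DANTE propagation handles zero time and the short-train fallback", {
  sch <- paperScheme(); comp <- paperComp()
  pops <- partitionPopulations(boundFraction(comp), sch)
  e0 <- CestExperiment(B1 = 10, Tsat = 0, irradiation = "dante",
                       danteWindow = 400, offsets = 0)
  M <- propagateDante(testSpin(), sch, pops, e0, offset = 0)
  expect_equal(M[3 * (1:4)], unname(populations(pops)), tolerance = 1e-12)
  eShort <- CestExperiment(B1 = 10, Tsat = 1e-3, irradiation = "dante",
                           danteWindow = 400, offsets = 0)
  expect_warning(propagateDante(testSpin(), sch, pops, eShort, offset = 0),
                 "falling back")
})

test_that("profile features: no saturation, full saturation, resolvable dips", {
  sch <- paperScheme(); comp <- paperComp()
  # vanishing B1: flat profile at the R1 baseline
  eF <- CestExperiment(B1 = 1e-4, Tsat = 0.4, irradiation = "cw",
                       offsets = seq(-500, 500, 100))
  pF <- simulateProfile(testSpin(), sch, comp, eF)
  expect_lt(diff(range(pF@intensities)), 1e-3)
  # strong on-resonance saturation kills the signal (rapidly relaxing spin)
  spinR <- testSpin(R2F = 25)
  eS <- CestExperiment(B1 = 500, Tsat = 0.4, irradiation = "cw",
                       offsets = (118 - 118.5) * 96.3)
  pS <- simulateProfile(spinR, sch, comp, eS)
  expect_lt(pS@intensities, 0.01)
  # widely split minor states give at least two resolvable local minima
  spinW <- testSpin(dwFA = 0, dwFB = 3, dwFC = 5, R2B = 20, R2C = 20)
  eW <- CestExperiment(B1 = 20.5, Tsat = 0.4, irradiation = "cw",
                       offsets = seq(-200, 700, 10))
  pW <- simulateProfile(spinW, sch, comp, eW)
  dips <- pickDips(pW, threshold = 5, sigma = 1e-4)
  expect_gte(nrow(dips), 2)
})

test_that("no-exchange dip sits at the major shift for all B1 fields", {
  sch0 <- ExchangeScheme("4site", kon = 0, koff = 1e-12, kAB = 1e-12,
                         kBA = 1e-12, kBC = 1e-12, kCB = 1e-12)
  comp0 <- MixtureComposition(500, 0, 24)
  for (b1 in c(5.2, 20.5, 68.6)) {
    e <- CestExperiment(B1 = b1, Tsat = 0.4, irradiation = "cw",
                        offsets = seq(-300, 300, 10))
    # R2 large enough to damp on-resonance Rabi oscillations within Tsat
    # (undamped coherent nutation legitimately displaces the raw minimum)
    p <- simulateProfile(testSpin(shiftF = 118.5, R2F = 25), sch0, comp0, e)
    # within one grid step; with a saturation-flattened bottom (large B1) the
    # profile at the resonance must be as deep as the numeric minimum
    ok <- abs(p@offsets[which.min(p@intensities)]) <= 10 ||
      p@intensities[p@offsets == 0] <= min(p@intensities) + 1e-8
    expect_true(ok)
  }
})

test_that("a 4-site scheme with empty downstream states reduces to two sites", {
  # K_eq,AB = 0 empties B and C; the chain becomes an active F<->A two-site
  # exchange that must match a direct 2-site simulation
  sch <- ExchangeScheme("4site", kon = 7.3e5, koff = 56, kAB = 0, kBA = 10,
                        kBC = 89, kCB = 94)
  comp <- paperComp()
  spin <- testSpin(dwFA = 3, dwFB = 1, dwFC = 2, R2A = 25)
  e <- cwExperiment(B1 = 20.5, offsets = seq(-500, 500, 25))
  pops <- populations(partitionPopulations(boundFraction(comp), sch))
  expect_equal(unname(pops[c("B", "C")]), c(0, 0))
  p4 <- simulateProfile(spin, sch, comp, e)@intensities
  # direct 2-site reference through the backend
  kfa <- 56 * pops[["A"]] / pops[["F"]]
  K2 <- matrix(c(-kfa, kfa, 56, -56), 2, 2)
  shifts <- (c(118, 121) - 118.5) * 96.3
  I2 <- drop(cestfold:::.cestProfileC(e@offsets, shifts,
                                      unname(pops[c("F", "A")]), K2, 1.3,
                                      c(5, 25), 20.5, 0.4, FALSE, 0))
  expect_lt(max(abs(p4 - I2)), 1e-6)
})

test_that("exclusion mask removes the on-resonance window", {
  sch <- paperScheme(); comp <- paperComp()
  e <- CestExperiment(B1 = 20.5, Tsat = 0.4, irradiation = "cw",
                      offsets = seq(-120, 120, 8), carrier = 118.5)
  spin <- testSpin(shiftF = 118.5, dwFA = 1, dwFB = 1, dwFC = 1)
  p <- simulateProfile(spin, sch, comp, e)
  # 8 Hz grid containing the resonance: points at 0, +/-8, +/-16 fall inside
  # +/-20.5 Hz
  expect_equal(sum(!exclusionMask(p, B1 = 20.5, majorShift = 118.5)), 5L)
  # window smaller than half the spacing with no point inside
  e2 <- CestExperiment(B1 = 3, Tsat = 0.4, irradiation = "cw",
                       offsets = seq(-120, 120, 8) + 4, carrier = 118.5)
  p2 <- simulateProfile(spin, sch, comp, e2)
  expect_true(all(exclusionMask(p2, B1 = 3, majorShift = 118.5)))
  # empty profile -> empty mask
  pe <- new("CestProfile", residueId = 1L, experiment = e,
            offsets = numeric(), intensities = numeric(), sigmas = numeric(),
            mask = logical())
  expect_identical(exclusionMask(pe), logical(0))
})
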