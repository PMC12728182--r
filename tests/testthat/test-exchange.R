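# Linear exchange kinetics: population algebra, macroscopic Kd, detailed
# balance.

# independent oracle: bisection on the mass-balance equation
# C (P0 - C)(R0 - C)/... i.e. f(C) = C^2 - C (P0+R0+Kd) + P0 R0
bisectBound <- function(P0, R0, Kd) {
  f <- function(C) C^2 - C * (P0 + R0 + Kd) + P0 * R0
  lo <- 0; hi <- min(P0, R0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2 / P0
}

test_that("bound fraction solves the mass-balance quadratic", {
  expect_equal(boundFraction(MixtureComposition(500, 100, 24)),
               bisectBound(500, 100, 24), tolerance = 1e-10)
  expect_equal(round(boundFraction(MixtureComposition(500, 100, 24)), 4),
               0.1888)
  # infinite-Kd limit and absent partner
  expect_lt(boundFraction(MixtureComposition(500, 100, 1e12)), 1e-6)
  expect_identical(boundFraction(MixtureComposition(500, 0, 24)), 0)
  expect_error(MixtureComposition(-1, 100, 24), "concentrations")
  expect_error(MixtureComposition(500, 100, -2))
})

test_that("bound fraction is monotone in Kd and partner concentration", {
  set.seed(42)
  for (i in 1:25) {
    P0 <- runif(1, 10, 1000); R0 <- runif(1, 10, 1000); Kd <- runif(1, 1, 500)
    f1 <- boundFraction(MixtureComposition(P0, R0, Kd))
    expect_gt(f1, boundFraction(MixtureComposition(P0, R0, Kd * 1.5)))
    expect_lt(f1, boundFraction(MixtureComposition(P0, R0 * 1.5, Kd)))
  }
})

test_that("population partition follows the per-step equilibrium constants", {
  schEq <- ExchangeScheme("4site", kon = 1e5, koff = 50, kAB = 10, kBA = 10,
                          kBC = 10, kCB = 10)
  p <- populations(partitionPopulations(0.3, schEq))
  expect_equal(unname(p), c(0.7, 0.1, 0.1, 0.1), tolerance = 1e-12)

  p2 <- populations(partitionPopulations(0.1888265, paperScheme()))
  expect_equal(round(unname(p2), 4), c(0.8112, 0.0592, 0.0666, 0.0630))

  p0 <- populations(partitionPopulations(0, paperScheme()))
  expect_equal(unname(p0), c(1, 0, 0, 0))
  expect_error(partitionPopulations(1.2, paperScheme()), "totalBound")
  expect_error(partitionPopulations(-0.1, paperScheme()), "totalBound")
})

test_that("stationary distribution of the rate matrix matches the partition", {
  sch <- paperScheme(); comp <- paperComp()
  K <- rateMatrix(sch, comp)
  expect_equal(colSums(K), setNames(rep(0, 4), stateLabels(sch)),
               tolerance = 1e-12)
  ev <- eigen(K)
  v <- Re(ev$vectors[, which.min(abs(ev$values))])
  v <- v / sum(v)
  p <- populations(partitionPopulations(boundFraction(comp), sch))
  expect_equal(v, unname(p), tolerance = 1e-10)
})

test_that("apparent Kd reproduces the macroscopic dissociation constant", {
  # the printed microscopic rates imply the measured overall Kd
  expect_equal(apparentKd(paperScheme()), 24, tolerance = 0.05 / 24)
  # downstream states unpopulated -> first-step Kd exactly
  schA <- ExchangeScheme("4site", kon = 1e6, koff = 50, kAB = 0, kBA = 10,
                         kBC = 20, kCB = 30)
  expect_equal(apparentKd(schA), 50 / 1e6 * 1e6, tolerance = 1e-12)
  # equal partition: Kd1 / 3
  schE <- ExchangeScheme("4site", kon = 1e6, koff = 30, kAB = 7, kBA = 7,
                         kBC = 9, kCB = 9)
  expect_equal(apparentKd(schE), 30 / 1e6 * 1e6 / 3, tolerance = 1e-12)
  expect_error(apparentKd(ExchangeScheme("4site", kon = 0, koff = 1,
                                         kAB = 1, kBA = 1, kBC = 1, kCB = 1)),
               "kon")
  expect_error(apparentKd(ExchangeScheme("4site", kon = 1, koff = 1,
                                         kAB = 1, kBA = 0, kBC = 1, kCB = 1)),
               "reverse")
})

test_that("3-site scheme drops the A state rather than zeroing rates", {
  sch3 <- ExchangeScheme("3site", kon = 7.3e5, koff = 56, kBC = 89, kCB = 94)
  expect_identical(stateLabels(sch3), c("F", "B", "C"))
  expect_equal(nStates(sch3), 3L)
  expect_equal(unname(apparentKd(sch3)),
               56 / 7.3e5 * 1e6 / (1 + 89 / 94), tolerance = 1e-12)
  K <- rateMatrix(sch3, paperComp())
  expect_equal(dim(K), c(3L, 3L))
  # strictly linear: no F<->C coupling
  expect_identical(K[1, 3], 0); expect_identical(K[3, 1], 0)
})

test_that("derived equilibrium and exchange constants are rate-consistent", {
  sch <- paperScheme()
  expect_equal(unname(keq(sch)), c(72 / 64, 89 / 94), tolerance = 1e-12)
  expect_equal(unname(kex(sch)), c(136, 183), tolerance = 1e-12)
  # config round trip preserves the rates exactly
  sch2 <- schemeFromConfig(schemeToConfig(sch))
  expect_equal(keq(sch2), keq(sch), tolerance = 1e-12)
  expect_equal(kex(sch2), kex(sch), tolerance = 1e-12)
})

test_that("pseudo-first-order closure is consistent with mass balance", {
  sch <- paperScheme(); comp <- paperComp()
  kfa <- pseudoFirstOrderRate(sch, comp)
  p <- populations(partitionPopulations(boundFraction(comp), sch))
  expect_equal(kfa, 56 * p[["A"]] / p[["F"]], tolerance = 1e-12)
  expect_equal(round(kfa, 2), 4.09, tolerance = 0.005)
  # kon * [R_free] equals koff * pA / pF under the constraint
  C <- boundFraction(comp) * 500
  expect_equal(7.3e5 * (100 - C) * 1e-6, kfa, tolerance = 2e-2)
  # no partner, no association
  expect_equal(pseudoFirstOrderRate(sch, MixtureComposition(500, 0, 24)) * 1,
               0, tolerance = 1e-12)
})
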