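# Shared fixtures: the reference kinetic scheme, small spin systems, reduced
# synthetic scenarios, and the ODE oracle used to validate matrix-exponential
# propagation.

paperScheme <- function() {
  ExchangeScheme("4site", kon = 7.3e5, koff = 56, kAB = 72, kBA = 64,
                 kBC = 89, kCB = 94)
}

paperComp <- function() MixtureComposition(P0 = 500, R0 = 100, Kd = 24)

paperGlobals <- function() {
  c(koff = 56, kexAB = 72 + 64, kexBC = 89 + 94,
    KeqAB = 72 / 64, KeqBC = 89 / 94)
}

testSpin <- function(residueId = 330L, shiftF = 118, dwFA = 2, dwFB = 2.2,
                     dwFC = 2.5, R1F = 1.3, R2F = 5, R2B = 25, R2C = R2B,
                     R2A = R2F) {
  ResidueSpinSystem(residueId, shiftF = shiftF, dwFA = dwFA, dwFB = dwFB,
                    dwFC = dwFC, R1F = R1F, R2F = R2F, R2B = R2B, R2C = R2C,
                    R2A = R2A)
}

cwExperiment <- function(B1 = 20.5, Tsat = 0.4, offsets = seq(-800, 800, 25),
                         carrier = 118.5) {
  CestExperiment(B1 = B1, Tsat = Tsat, irradiation = "cw", carrier = carrier,
                 offsets = offsets)
}

# reduced experiment grid: one D-CEST window plus the CW field, coarse steps
tinyExperiments <- function(cwStep = 100) {
  list(
    CestExperiment(B1 = 20.5, Tsat = 0.4, irradiation = "dante",
                   danteWindow = 800, offsets = seq(-384, 384, 32)),
    CestExperiment(B1 = 68.6, Tsat = 0.4, irradiation = "cw",
                   offsets = seq(-1492, 1493, cwStep)))
}

# small scenario used by the fast fitting tests: one residue per class
tinyScenario <- function(seed = 1, sigma = 0.004,
                         experiments = tinyExperiments()) {
  makeDefaultScenario(seed = seed, sigma = sigma,
                      cribResidues = 325L, mre1Residues = 340L,
                      mre2Residues = 358L, linkerResidues = integer(),
                      experiments = experiments)
}

# adaptive-ODE oracle for the Bloch-McConnell evolution, independent of the
# matrix-exponential production path
odePropagate <- function(G, M0, t) {
  out <- deSolve::ode(y = M0, times = c(0, t), parms = NULL,
                      func = function(t, y, p) list(as.vector(G %*% y)),
                      rtol = 1e-10, atol = 1e-12, maxsteps = 500000)
  as.numeric(out[2, -1])
}

# random valid spin/scheme/offset instance for property tests
randomInstance <- function() {
  sch <- ExchangeScheme("4site", kon = 7.3e5,
                        koff = runif(1, 10, 200), kAB = runif(1, 10, 200),
                        kBA = runif(1, 10, 200), kBC = runif(1, 10, 200),
                        kCB = runif(1, 10, 200))
  spin <- testSpin(dwFA = runif(1, -4, 4), dwFB = runif(1, -5, 5),
                   dwFC = runif(1, -6, 6), R1F = runif(1, 0.5, 3),
                   R2F = runif(1, 2, 10), R2B = runif(1, 10, 40),
                   R2C = runif(1, 10, 40))
  comp <- MixtureComposition(500, runif(1, 20, 200), runif(1, 5, 100))
  expt <- cwExperiment(B1 = runif(1, 5, 70))
  offset <- runif(1, -600, 600)
  list(scheme = sch, spin = spin, comp = comp, expt = expt, offset = offset)
}
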