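---
title: "Quantifying hierarchical folding-upon-binding from CEST, relaxation and ITC data"
author: "cestfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hierarchical folding-upon-binding from CEST, relaxation and ITC data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cestfold)
```

## The scientific problem

Many intrinsically disordered protein (IDP) regions fold only when they bind
a partner. When the folding proceeds through on-pathway intermediates, the
bound intermediates are weakly populated (a few percent) and invisible to
conventional NMR observables, but they leave clear fingerprints in
^15^N chemical exchange saturation transfer (CEST) profiles: each exchanging
state produces a dip at its own chemical shift, with a depth governed by its
population and exchange kinetics. `cestfold` implements the complete
quantitative chain for such systems:

1. an **N-site linear Bloch-McConnell forward model** of CEST profiles under
   continuous-wave or DANTE (D-CEST) saturation;
2. a **staged fitting protocol** -- residue-specific 3-site fits, minor-state
   assignment with a swap test, then constrained global 3-site and 4-site
   fits, nested-model comparison and bootstrap uncertainties;
3. **R1rho decay fitting** with Monte Carlo errors (binding reporter);
4. an **ITC thermodynamic layer** -- one-set-of-sites fitting of
   concatenated injections across temperature, heat capacity and
   iso-entropic temperature regression, and a Spolar-Record entropy
   decomposition that converts the conformational entropy of binding into an
   estimate of the number of residues folding upon binding;
5. a **synthetic-data generator** that emulates the assumed data structure
   with known ground truth, so every stage is validated by parameter
   recovery.

The driving application is a disordered effector region binding a small
GTPase through a partial CRIB (Cdc42/Rac1-interactive binding) anchor
followed by sequential folding of two molecular recognition elements (MRE1:
strand + helix; MRE2: beta-hairpin), i.e. a linear kinetic chain

F + partner <-> A (anchored) <-> B (MRE1 folded) <-> C (fully folded),

with microscopic rates kon, koff, kAB, kBA, kBC, kCB. The linear topology is
a modelling assumption justified by the hierarchy of the folding process
(anchor mutations abolish binding entirely; the second element packs against
the first); branched or cyclic schemes are out of scope.

## The exchange model and its constraints

### Populations are fixed by the sample composition

The total bound fraction is not a fit parameter. With total IDP
concentration $P_0$, partner concentration $R_0$ and overall dissociation
constant $K_d$ (from ITC), the complex concentration $C$ solves

$$C^2 - C\,(P_0 + R_0 + K_d) + P_0 R_0 = 0,$$

and only the smaller root is physical ($C \le \min(P_0, R_0)$);
`boundFraction()` evaluates it in a cancellation-safe form. The bound
fraction is then distributed over the chain's bound states by the per-step
equilibrium constants ($K_{AB} = k_{AB}/k_{BA} = p_B/p_A$, similarly
$K_{BC}$), in `partitionPopulations()`. At every optimizer iteration the
populations therefore satisfy the constraint exactly -- "constraint
conservation" is structural, not numerical.

The first (bimolecular) step enters the spin dynamics as a pseudo-first-order
rate fixed by detailed balance, $k_{F\to A} = k_{off}\, p_A / p_F$, so kon
never appears in the likelihood. It is derived *post hoc* from the fitted
koff, the constrained populations and the free-partner concentration
(`deriveKon()`); the macroscopic consistency relation

$$K_d^{app} = \frac{k_{off}/k_{on}}{1 + K_{AB}(1 + K_{BC})}$$

(`apparentKd()`) closes the loop between the kinetic and thermodynamic
measurements.

### Bloch-McConnell propagation

The spin basis is three Cartesian components per ^15^N state (in-phase
magnetization only). Scalar coupling, proton CSA/NOE and detection-period
details are not modelled: the fitted quantities (shift differences,
populations, rates) are insensitive to them at this fidelity, and an
external-lock acquisition scheme suppresses amide-exchange artefacts in the
data this model targets. Longitudinal relaxation drives $M_z$ to zero (no
recovery term) and the observable is the summed z-magnetization after the
saturation period, normalized by a zero-length-saturation reference; the
far-off-resonance baseline is then exactly $\exp(-R_{1F} T_{sat})$, an
assertable closed form. One longitudinal rate per residue is shared by all
states (minor-state R1 is unidentifiable at ~6 % populations).

CW saturation is propagated by the matrix exponential of the 3N x 3N
generator (RcppArmadillo backend; validated against an adaptive ODE oracle
to 1e-8). D-CEST saturation is modelled as a train of ideal delta pulses of
flip angle $2\pi B_1/w$ separated by free precession $1/w$, where $w$ is the
DANTE window; the per-period propagator is applied
$\mathrm{round}(T_{sat} w)$ times. Two consequences are used as tests: the
profile is periodic in the offset with period $w$ (frequency-comb
aliasing), and within the principal band the D-CEST profile matches CW at
the same nominal $B_1$ (to 0.02 for $B_1 \le 25$ Hz). B1 inhomogeneity is
not modelled; the analysis excludes the on-resonance window
(+/- B1 in Hz of the major resonance, `exclusionMask()`) where it would
dominate.

ppm-to-Hz conversion happens in exactly one place (`ppmToHz()`), using the
configured ^15^N Larmor frequency with ppm increasing downfield; offsets are
stored in Hz internally.

## The staged inference

Noise is estimated per profile with a second-difference filter,
$\hat\sigma^2 = \sum (y_{i-1} - 2y_i + y_{i+1})^2 / (6(N-2))$, which
annihilates smooth trends and works without extended baselines.

**Stage 1 (residue-specific 3-site fits)** fit koff, kBC, kCB, the two shift
differences, R1F, R2F and R2B (= R2C) per residue across all B1 fields, with
the bound-population sum fixed. Starting shift differences come from an
alias-aware dip deconvolution: each D-CEST dip determines the minor-state
position only modulo the DANTE window, so dips are expanded into their alias
ladders and clustered across windows and the unaliased CW profile -- the true
position recurs everywhere while alias ghosts disagree. A coarse
chi-square scan over candidate (dwFB, dwFC) pairs (including 0 and +/-0.3 ppm
satellites, over a small grid of nominal minor-state R2 values) selects the
starting configuration; bounded Levenberg-Marquardt (minpack.lm) with
multi-start jitter (+/-50 % on rates, +/-0.3-0.4 ppm on shifts) refines it.

**Stage 2 (assignment)** labels the dip closest to the major state as the
intermediate B and the farthest as the complex C, then refits with the
labels exchanged; the original assignment is accepted when the swap
increases the residuals or reverts (`assignMinorStates()`).

**Stage 3 (global fits)** share koff, kBC, kCB (3-site) or koff, kexAB,
kexBC, KeqAB, KeqBC (4-site) across residues. For the 4-site model, R2A is
tied to R2B inside the anchoring-motif set and to R2F outside it (outside
the motif the anchored intermediate is still disordered), dwFA is
initialized at dwFB inside the motif and 0 outside, and an optional
R2B = R2C tie stabilizes residues with overlapping minor states. A non-motif
residue whose 3-site intermediate collapsed onto the free state is
re-initialized with dwFB at the bound position (its at-zero feature is the
anchored state A in the 4-site reading).

The joint least-squares problem couples ~5 global to 7-9 parameters per
residue, and the compartments can compensate (a wrong population split is
absorbed by minor-state R2 values), creating broad correlated local minima.
`fitGlobalStaged()` therefore (i) branches over a coarse grid of KeqAB
(1, 0.5, 2) -- the one global parameter the 3-site stage cannot inform;
(ii) within a branch alternates globals-only fits with per-residue re-scans
and local refits, the warm-up refits carrying the R2B = R2C tie so that a
wrong population split cannot be absorbed into split minor-state R2 values;
and (iii) finishes with the full joint Levenberg-Marquardt fit (ties
released) plus a final per-residue swap-test sweep. A branch is accepted
once its joint fit is consistent with the noise (chi-square per point
below 2) *and* shows no minor-state R2 collapsed toward zero while the
free-state R2 stays normal -- the signature of the population/relaxation
compensation valley; otherwise the remaining branches are tried and the
best joint fit kept. Convergence is declared at a relative
chi-square change below 1e-8; shift differences are bounded to +/-20 ppm and
rates to (1e-3, 1e4) s^-1 (physically generous, numerically stabilizing);
positive parameters are optimized on a log10 scale. The major-state position
itself is refined within +/-0.12 ppm of its data-driven estimate (in real
data it would be fixed from assigned peak positions; when it must be
estimated from profile minima, leaving it fixed propagates a few-Hz
quantization error into every residual).

**Model comparison** uses the F-test on the nested least-squares fits at
alpha = 0.05, the canonical choice for nested chi-square models.
**Uncertainties** come from the covariance of the Levenberg-Marquardt fit
and from a bootstrap that resamples each profile's points with replacement
(sizes preserved; implemented as multiplicity weights so the offset grid
stays valid -- the chi-square is identical to literal duplication), refits
each replicate from the point estimate, and reports 68 % percentile
intervals. Replicates run at a relaxed objective tolerance (relative
chi-square change 1e-6): they start at the point optimum, and the strict
tolerance of the point fit would merely crawl along the same flat
directions whose width the replicate spread is measuring. Non-converging
replicates are dropped and counted.
**Boundary search** (`searchCribBoundary()`) enumerates (lower, upper)
residue limits of the anchoring motif, refits globally for each, and keeps
the subset with minimal residuals; `gridSearch()` profiles the chi-square
surface over (kexAB, kexBC) with all other parameters re-optimized.

## Relaxation and ITC layers

R1rho decays are fit as $I(t) = I_0 e^{-Rt}$ on the linear intensity scale
with uniform weights (a log transform would distort the noise at late
delays); negative intensities are retained, since flooring biases the rate
upward at low signal-to-noise. The delay schedule 1, 10, 30, 50, 70 (x2),
90, 130, 170, 210, 250 ms enters with the duplicate as two independent
observations. Uncertainties come from Monte Carlo resampling with the
per-plane noise (default 500 draws, a stated choice).

ITC injections follow the standard perfusion-cell displacement model: each
injection dilutes both species by $(1 - dV/V_0)$ while titrant accumulates;
the bound concentration is the physical root of the single-site quadratic
with $n$ equivalent sites, and the injection heat is
$\Delta H V_0 (B_i - B_{i-1}(1 - dV_i/V_0)) + q_{offset}$. Concatenated
segments (syringe refills into the same cell content) share one parameter
set. The additive offset absorbs small systematic heats instead of
discarding first injections (an exclusion flag exists). The default cell
volume is 200 uL, the nominal working volume of the instrument class used
for such measurements. The standard state for $\Delta G = RT \ln K_d$ is
1 M -- required for the printed $K_d \leftrightarrow \Delta G$ magnitudes to
be mutually consistent.

Per-temperature one-site fits give $(K_d, \Delta H)$; $\Delta S$ is computed
per temperature as $(\Delta H - \Delta G)/T$ and regressed against $T$
(mirroring how all three quantities are plotted in such studies), giving the
heat capacity $\Delta C_p$ (slope of $\Delta H$ vs $T$), the iso-entropic
temperature $T_S$ (zero crossing of $\Delta S$ vs $T$) and the Kd
extrapolation to 25 C via the linear fit of $\Delta G$ vs $T$. Note that
under a constant $\Delta C_p$, $\Delta G(T)$ is curved; the linear
extrapolation inherits a quantifiable curvature offset (the tests pin it
against a closed-form oracle rather than asserting it away). The
Spolar-Record decomposition, re-parameterized for IDP complexes, is

$$\Delta S^\circ_{conf} = -1.66\,\Delta C_p \ln(T_S/386\,K) + 110\ \mathrm{J\,mol^{-1}K^{-1}},
\qquad \Delta S_{desolv}(T) = 1.66\,\Delta C_p \ln(T/386\,K),
\qquad \Delta S_{rt} = -110,$$

whose total vanishes at $T = T_S$ by construction (asserted to 1e-9).
Dividing the conformational term by an average per-residue loss of
-24 J mol^-1 K^-1 estimates the number of residues folding upon binding;
with the measured $\Delta C_p = -2.8$ kJ mol^-1 K^-1 and $T_S = 307.1$ K
this gives about 40 residues.

## What the synthetic generator emulates -- and what it does not

`makeDefaultScenario()` encodes the shift-difference classes of hierarchical
folding: anchoring-motif residues are already shifted in the anchored
intermediate (|dwFA| in 1-4 ppm, dwFB = dwFA, dwFC nearby), helix residues
shift upon the first folding step (dwFA = 0, |dwFB| in 1-5 ppm), hairpin
residues are partially shifted in the intermediate (dwFB a 0.2-0.8 fraction
of dwFC, |dwFC| in 1-6 ppm) and linker residues carry no shifts. In the
anchored intermediate, only motif residues relax like the bound state; all
others still relax like the free state. The default roster has 12 residues
(five anchoring -- 325, 327, 330, 331, 333, matching the boundary-search
truth -- three helix, three hairpin, one linker): large enough to exercise
every class and the boundary search, small enough for desk-scale recovery
runs. The experiment grid is three D-CEST fields (5.2, 10.3, 20.5 Hz with
windows 240, 448, 800 Hz stepped at 8, 16, 32 Hz) plus one CW field
(68.6 Hz stepped at 100 Hz across 103-134 ppm), 0.4 s saturation, 96.3 MHz
^15^N at 118.5 ppm carrier. Noise is homoscedastic Gaussian per profile
(fraction 0.004 of the reference by default), matching the single-sigma
noise model of the analysis.

Not emulated: spectral overlap and peak-picking from raw spectra, amide
solvent-exchange artefacts, B1 inhomogeneity, temperature instability, and
heteroscedastic noise. Passing recovery tests therefore demonstrate the
correctness and identifiability of the analysis chain under its own
assumptions -- not robustness to the full pathology of experimental spectra.

## Numerical choices, degeneracies and limitations

* **Coincident minor states.** When dwFB and dwFC agree within their
  linewidths, the B/C labelling is exchange-degenerate: the fitted pair of
  positions is precise but the labels may swap. The swap-test sweep resolves
  most cases; recovery tests compare labels only for separations of at least
  1 ppm and positions label-free below that.
* **Rabi oscillations.** With no exchange and slow transverse relaxation,
  the on-resonance magnetization nutates coherently and the raw profile
  minimum can sit off-resonance; the dip-position invariant holds once R2
  damps the oscillation within the saturation period.
* **Populations vs minor-state R2.** These compensate along broad valleys;
  the KeqAB branch scan plus alternation is the package's answer, and the
  R2B = R2C tie is available where overlapping minor states need it.
* **Problem sizes.** The recovery suite uses the 12-residue default
  scenario for the headline run and 1-3-residue scenarios with a reduced
  two-field grid for simulation studies (model-comparison power and size,
  bootstrap coverage), chosen so the whole validation remains a desk-scale
  computation.
* **Linear chain only.** No branched or cyclic topologies; the 3-site model
  is represented as a chain with the anchored state deleted, not with
  zeroed rates, keeping generators non-singular.

## A worked example

```{r example}
library(cestfold)

scenario <- makeDefaultScenario(seed = 11, sigma = 0.004)
gen <- generateCestDataset(scenario)
res <- runCestPipeline(gen$dataset, model = "4site",
                       cribRange = c(325, 333), seed = 5)
res$fit4
res$kon
res$comparison

gt <- generateTitrations(sigmaQ = 0, seed = 2)
tp <- runThermoPipeline(gt$series)
tp$dCp; tp$TS
tp$decomposition
```
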