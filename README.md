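# cestfold

Quantitative analysis of **hierarchical folding-upon-binding** of
intrinsically disordered protein (IDP) regions, from three complementary
measurements:

* **¹⁵N CEST** (chemical exchange saturation transfer) profiles under
  continuous-wave or DANTE (D-CEST) saturation, forward-modelled with the
  N-site Bloch–McConnell equations for a strictly linear exchange chain

  F + partner ⇌ A (anchored) ⇌ B (first element folded) ⇌ C (fully folded),

  and fit by a staged protocol: residue-specific 3-site fits →
  minor-state assignment with a swap test → constrained global 3-site and
  4-site fits → nested F-test model comparison → bootstrap uncertainties.
  The bound-state population sum is never fitted: it is fixed from the
  sample composition and the ITC dissociation constant through the
  mass-balance quadratic, and distributed over the bound states by the
  per-step equilibrium constants. The bimolecular on-rate is derived
  afterwards from detailed balance, and the microscopic rates must
  reproduce the macroscopic affinity through

  K_d(app) = (k_off/k_on) / (1 + K_AB (1 + K_BC)).

* **¹⁵N R₁ρ decays**, fit as single exponentials with Monte Carlo error
  propagation from per-plane noise.

* **ITC titrations across temperature**: one-set-of-sites fitting of
  concatenated injection series, ΔC_p as the slope of ΔH vs T, the
  iso-entropic temperature T_S as the zero crossing of ΔS vs T, and the
  Spolar–Record decomposition

  ΔS°_conf = −1.66 ΔC_p ln(T_S / 386 K) + 110 J mol⁻¹ K⁻¹,

  whose conformational term, divided by an average per-residue entropy loss
  of −24 J mol⁻¹ K⁻¹, estimates how many residues fold upon binding.

A first-class **synthetic-data generator** emulates the shift-difference
class structure of hierarchical folding (anchor residues shifted already in
A; helix residues shifted in B; hairpin residues partially shifted in B,
fully in C), the D-CEST/CW experiment grid, the relaxation delay schedule
and temperature-series titrations — with recorded ground truth, so every
stage of the analysis is validated by parameter recovery.

## Worked example

```r
library(cestfold)

## thermodynamics: synthetic titrations from the anchor
## Kd(25 °C) = 24 uM, dH(25 °C) = 0, dCp = -2.8 kJ/mol/K
gt <- generateTitrations(sigmaQ = 0, seed = 2)
tp <- runThermoPipeline(gt$series)
tp$dCp
#> [1] -2.8
tp$TS
#> [1] 307.661
tp$decomposition
#> Entropy decomposition at 298.15 K (T_S = 307.66 K, dCp = -2.8 kJ/mol/K):
#>   dS_conf     =   -944.3 J/mol/K
#>   dS_desolv   =   1200.3 J/mol/K
#>   dS_rt       =   -110.0 J/mol/K
#>   dS_total    =    146.0 J/mol/K
#>   ~39 residues fold upon binding (at -24 J/mol/K per residue)
```

The fitted ΔH-vs-T slope returns the generating heat capacity exactly, the
entropy zero crossing lands at 307.7 K, and the decomposition says that
roughly forty residues trade conformational freedom for desolvation — the
entropic signature of folding-upon-binding. With the published calorimetric
constants (ΔC_p = −2.8 kJ mol⁻¹ K⁻¹, T_S = 307.1 K) the same closed form
gives exactly 40:

```r
spolarRecord(dCp = -2.8, TS = 307.1)
#> Entropy decomposition at 298.15 K (T_S = 307.10 K, dCp = -2.8 kJ/mol/K):
#>   dS_conf     =   -952.8 J/mol/K
#>   dS_desolv   =   1200.3 J/mol/K
#>   dS_rt       =   -110.0 J/mol/K
#>   dS_total    =    137.5 J/mol/K
#>   ~40 residues fold upon binding (at -24 J/mol/K per residue)
```

Kinetics — generate a synthetic CEST dataset with the reference 4-site
rates as ground truth and recover them with the staged global fit (takes a
few minutes):

```r
scenario <- makeDefaultScenario(seed = 1, sigma = 0.004)
gen <- generateCestDataset(scenario)
res <- runCestPipeline(gen$dataset, model = "4site",
                       cribRange = c(325, 333), seed = 2,
                       nStartsResidue = 2)
res$fit4
#> 4site global fit: chi2 = 1231 over 1332 points, 101 parameters (dof 1231)
#>   koff   = 56.31 +/- 0.869
#>   kexAB  = 137 +/- 2.12
#>   kexBC  = 180.7 +/- 4.22
#>   KeqAB  = 1.123 +/- 0.0233
#>   KeqBC  = 0.9439 +/- 0.0202
res$kon
#> [1] 737002.3
res$comparison$decision
#> [1] "4site"
```

The generating values were koff = 56 s⁻¹, kexAB = 136 s⁻¹, kexBC = 183 s⁻¹,
KeqAB = 1.125, KeqBC = 0.947 and kon = 7.3×10⁵ M⁻¹s⁻¹: every global
exchange parameter is recovered within about one standard error, the fit is
statistically indistinguishable from the noise floor (χ² ≈ dof), and the
F-test prefers the 4-site mechanism over the nested 3-site alternative.

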