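# fibrilSANS

Small-angle neutron scattering (SANS) analysis of cellulose microfibril
bundling in plant cell walls.

In wood, cellulose microfibrils (2–3 nm thick, partially crystalline) are
packed side by side a few nanometres apart and aggregated laterally into
bundles (macrofibrils) some 10–20 nm across. Because the sample is a fiber
— microfibrils aligned with the cell axis — the lateral structure scatters
into an *equatorial* streak on a 2D SANS detector. `fibrilSANS` implements
the full analysis chain from 2D detector frames to bundle diameter and
interfibrillar spacing, for SANS instrument scientists and cell-wall
structural biologists:

1. **Reduction** — per-pixel q/azimuth mapping
   (q = 4π sin θ/λ, 2θ = atan(r/SDD)), azimuthal sectoring, subtraction of
   the isotropic component at each q, merging across detector distances,
   log rebinning.
2. **Model fitting** — the equatorial intensity is fitted with

   I(q) = A_mf ⟨Φ²(qR)⟩ S_N(q) + A_b exp(−q²/2σ_b²) + B q^(−α) + C

   where Φ(x) = 2J₁(x)/x is the cylinder cross-section amplitude averaged
   over a truncated-normal radius distribution, S_N is a finite 1D
   paracrystalline structure factor along the hexagonal {100} packing
   direction (spacing d₁₀₀ = (√3/2)·a_cc, distortion g, N coherent
   planes), the Gaussian is the bundle term, and the power law (α = 4,
   Porod) describes large water-filled pores and cell lumina.
3. **Structure** — equating the bundle Gaussian with the cross-section
   Guinier law exp(−q²R_c²/2) gives R_c = 1/σ_b; for a homogeneous
   circular cross-section D = 2√2/σ_b. The packing peak at
   q ≈ 2π/d₁₀₀ (0.1–0.2 Å⁻¹) gives the center-to-center spacing a_cc.
4. **Contrast planning** — neutron scattering-length densities
   ρ = Σᵢ nᵢ b_coh,i/V from a bundled table, with solvent H/D exchange,
   for reasoning about contrast matching (e.g. PEG-filled pores in D₂O).
5. **Solution sizing** — Guinier and Debye (Gaussian-coil) fits for
   polymers such as PEG in solution.
6. **Synthetic data** — seeded generators of 1D profiles and
   multi-distance 2D frames (D11-like: λ = 6 Å, SDD 1.5/8/39 m,
   q = 0.002–0.3 Å⁻¹, wrapped-Gaussian orientation smearing, Poisson
   noise) with known ground truth, so every stage is testable without
   instrument data.

## Worked example

Simulate a native-softwood measurement (spacing 4.3 nm, bundle diameter
18.5 nm) at three detector distances, reduce, and refit:

```r
library(fibrilSANS)

truth <- WoodModelParams(aCC = 43, sigma_b = 2 * sqrt(2) / 185)
spec  <- SyntheticSpec(truth = truth, seed = 42)
sim   <- generateFrames(spec)

prof <- reduceFrames(sim$frames)   # equatorial, anisotropic, merged
prof
#> Profile1D: 90 points, q in [0.001112, 0.3191] 1/A (relative units)
#>   merged from 3 configurations

fit <- fitEquatorial(prof, FitConfig(seed = 1))
derivedStructure(fit)
#> DerivedStructure: bundle diameter 18.72 nm, interfibrillar distance
#> 4.33 nm, packing peak 0.1566 1/A
```

The generating truth (18.5 nm, 4.3 nm) is recovered to ~1%. The bundle
diameter comes from the fitted Gaussian width, the spacing from the
paracrystal term; `decomposeContributions(prof, fit)` returns the
per-term curves plus the "data from bundles" residual (data minus the
fitted microfibril and pore terms).

Scattering-length densities for contrast reasoning:

```r
computeSLD(materialPreset("d2o"))
#> SLD [d2o]: 6.361e-06 1/A^2 (6.361 x 1e-6 1/A^2)
```

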