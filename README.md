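# mesogelkit

Multiscale modelling toolkit for lamellar liquid-crystalline drug-delivery
gels built from glyceryl monooleate (GMO), water, ethanol and a hydrophobic
drug (resveratrol). It is aimed at formulation scientists and
coarse-grained-simulation practitioners who want the full computational
chain of such a system in one tested, reproducible package:

1. **Thermodynamic bridging** — Flory–Huggins interaction parameters from
   solubility parameters, χᵢⱼ = (δᵢ − δⱼ)² V_ref / (RT), or from
   cohesive-energy densities via the mixing energy
   ΔE_mix = Φᵢ(E_coh/V)ᵢ + Φⱼ(E_coh/V)ⱼ − (E_coh/V)_mix; then the linear
   bridge to dissipative-particle-dynamics repulsions,
   **aᵢⱼ = 16.5 + 1.45 χᵢⱼ** (calibrated at ρ = 5, T = 328 K).
2. **A compiled Groot–Warren DPD engine** — soft pairwise repulsion with a
   momentum-conserving dissipative/random thermostat
   (σ² = 2γk_BT), bead-spring GMO chains (5 head + 16 tail beads, harmonic
   bonds with C = 4.0), modified velocity-Verlet integration, cell-list
   neighbour search, bit-reproducible under a seed.
3. **Mesophase diagnostics** — cloud-in-cell density fields, marching-
   tetrahedra iso-density surfaces, static structure factors
   S(q) = |Σ e^{iq·r}|²/N on the box-commensurate lattice (lamellar spacing
   d = 2π/q₁), and interfacial-enrichment scores for ethanol and drug.
4. **Kinetics** — release-model fitting (zero-order kt, Higuchi kt^½,
   Ritger–Peppas ktⁿ) with correlation-based model selection, and
   Franz-cell bookkeeping: Qₙ = CₙV_r + V_s ΣC_i and steady-state flux
   J_ss = slope/area with automatic linear-window detection.
5. **Synthetic data** — seeded generators for release curves, permeation
   curves, perfect lamellar configurations and small amphiphile fixtures,
   so every stage is testable without laboratory data.

## Worked example

```r
library(mesogelkit)

# bridge the packaged Flory-Huggins values to DPD repulsions
it <- rolg_interaction_table()
it
#> <interaction_table> 5 species: water, ethanol, resveratrol, A, B
#>   bridge a = 16.5 + 1.45 chi  (rho = 5, T = 328 K, V_ref = 18 cm^3/mol)
#>             water ethanol resveratrol     A     B
#> water       16.50   16.40       15.41 12.09 23.90
#> ethanol     16.40   16.50       16.99 15.92 17.20
#> resveratrol 15.41   16.99       16.50 14.73 16.60
#> A           12.09   15.92       14.73 16.50 17.99
#> B           23.90   17.20       16.60 17.99 16.50

round(drug_loading(rolg_formulation()), 1)  # mg drug per g gel
#> [1] 4.4

# which release law explains the gel's sustained release?
select_model(gen_release(preset = "reference_gel"))
#>    rank model             k     n     r n_params
#>    1    ritger_peppas 0.165 0.721 1            2
#>    2    higuchi       0.236 0.5   0.996        1
#>    3    zero_order    0.100 1     0.995        1

# steady-state transcorneal flux from the reference permeation points
steady_state_flux(gen_permeation(preset = "reference_gel"), area = 0.5)
#> <flux_fit> Jss = 275 ug/cm^2/h (slope 137.5 ug/h over 3 points), lag = 0 h
```

The large water/tail repulsion (a = 23.9) against the mild head/water
attraction drives microphase separation into alternating lipid/water
channels; the Ritger–Peppas exponent n ≈ 0.72 indicates
erosion-influenced rather than purely diffusive release.

A full simulation run — bead apportionment of the 27,302-bead reference
composition, DPD assembly, structure factors, iso-surfaces and enrichment
scores, with a manifest of all artifacts — is one call:

```r
run_pipeline(default_pipeline_config())   # or a YAML config via
                                          # read_pipeline_config("run.yaml")
```

Desk-scale settings (smaller box, fewer steps) are plain config overrides;
see `?default_pipeline_config`.

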