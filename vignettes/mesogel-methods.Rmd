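---
title: "Multiscale modelling of a lamellar GMO gel: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale modelling of a lamellar GMO gel: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesogelkit)
```

`mesogelkit` models a lyotropic lamellar liquid-crystalline gel of glyceryl
monooleate (GMO), water, ethanol and a hydrophobic drug (resveratrol) across
three scales: thermodynamic bridging from atomistic quantities to
coarse-grained interaction parameters, dissipative particle dynamics (DPD)
of the self-assembling mesophase, and empirical kinetics of drug release
and transcorneal permeation. This vignette records the models, their
assumptions, the tunable parameters and the design decisions that were
genuinely open.

## 1. From solubility parameters to DPD repulsions

For a pair of species without specific interactions, the Flory–Huggins
parameter follows from solubility parameters
$\delta$ ((J/cm³)^0.5^):

$$\chi_{ij} = \frac{(\delta_i - \delta_j)^2\, V_{ref}}{R\,T},$$

and for hydrogen-bonding pairs from cohesive-energy densities of the pure
components and the mixture:

$$\Delta E_{mix} = \Phi_i \left(\tfrac{E_{coh}}{V}\right)_i +
  \Phi_j \left(\tfrac{E_{coh}}{V}\right)_j -
  \left(\tfrac{E_{coh}}{V}\right)_{mix},
  \qquad \chi_{ij} = \frac{\Delta E_{mix}\,V_{ref}}{R\,T}.$$

The linear bridge to the DPD conservative repulsion, calibrated at reduced
bead density $\rho = 5$ and $T = 328\,$K, is

$$a_{ij} = 16.5 + 1.45\,\chi_{ij},$$

with the like-species baseline $a_{ii} = 16.5$. Units are enforced by
convention: $\delta^2$ in J/cm³ and $V_{ref}$ in cm³/mol make $\chi$
dimensionless with $R = 8.314$ J/(mol·K).

**Reference volume.** The source data for the gel system never states
$V_{ref}$. We default to $V_{ref} = 18$ cm³/mol, the molar volume of water
— the smallest bead and the usual convention when one water molecule is
one bead. Back-solving the water/tail-fragment row of the reference
$\chi$ table from the printed $\delta$ values would instead require
$V_{ref} \approx 18.7$ cm³/mol; both values are documented and `v_ref` is
an explicit argument everywhere, so neither is silently preferred. The
packaged $\chi$ values are consumed as reported inputs, not recomputed
from $\delta$.

**Internal inconsistencies.** Two of the ten reported $(\chi, a)$ pairs do
not satisfy the bridge at one-decimal rounding ($\chi = -1.22$ prints
14.9 where the bridge gives 14.7; $\chi = -0.40$ prints 16.1 vs 15.9).
The implementation always follows the bridge; `rolg_chi_pairs()` carries
both the printed and the recomputed column with a `consistent` flag, and
`check_bridge_consistency()` applies the same audit to any user table.

**Bead bookkeeping.** The coarse-graining maps one water molecule to one
bead, ethanol to a 3-bead chain, resveratrol to a 5-bead chain, and GMO to
an indivisible 21-bead chain (5 hydrophilic head beads "A", 16 hydrophobic
tail beads "B"). `bead_counts_from_formulation()` converts component
masses to mole fractions and apportions a requested bead budget into whole
molecules by largest-remainder rounding, adding molecules in remainder
order only while they fit the outstanding deficit (ties broken by
component order, so the result is deterministic). The realised total never
overshoots and is exact whenever a 1-bead species is present; bead
fractions converge to the exact mole-weighted targets as the budget grows.

## 2. The DPD engine

The engine implements the standard Groot–Warren force field in reduced
units ($r_c = m = k_BT = 1$): soft conservative repulsion
$a_{ij}(1 - r)\hat r$ for $r < 1$, pairwise dissipative force
$-\gamma w(r)^2 (\hat r \cdot v_{ij})\hat r$ and random force
$\sigma w(r) \theta_{ij} \hat r / \sqrt{\Delta t}$ with $w(r) = 1 - r$,
$\sigma^2 = 2\gamma k_BT$ and symmetric per-pair noise, so every
contribution — including the thermostat — conserves momentum exactly.
GMO chains are zero-rest-length harmonic springs $F = -C r$ with
$C = 4.0$ between consecutive beads. Integration is the modified
velocity-Verlet scheme with velocity-prediction factor $\lambda$; with
$\gamma = 0$ it reduces to plain velocity-Verlet (verified against the
analytic period of a bonded dimer).

Parameter defaults and why:

* `gamma = 4.5` — the standard DPD friction; the source description leaves
  it unstated. $\sigma$ is always derived from the fluctuation–dissipation
  relation, never set directly.
* `lambda = 0.65` — the conventional choice for which the kinetic
  temperature error stays small at practical timesteps. Our checks give
  mean $T^*$ within 0.5% of 1 at `dt = 0.04` and a monotone growth of the
  bias with `dt` (≈22% at `dt = 0.1`).
* `dt = 0.04` reduced time. The reference description quotes a physical
  "1.0 ps per step" without a unit mapping; the engine works purely in
  reduced units and only records an optional `time_scale` for reporting.
* Reduced mass 1 for every bead; $r_c = 1$ defines the length unit.

**Density discrepancy.** The reference system quotes 27,302 beads in a
20³ box — reduced density 3.41 — while the $\chi \to a$ bridge is
calibrated at $\rho = 5$. `run_pipeline()` honours the bead count and box
by default and warns about the mismatch; `system$match_density = TRUE`
rescales the box to $\rho = 5$ instead. Desk-scale analyses in the test
suite use density 3.41, which demixes robustly under the bridged
repulsions.

**Determinism.** All initial placement uses R's RNG under a caller seed;
the engine's per-pair noise uses its own splitmix-based counter generator
with uniform unit-variance noise, so a (state, parameters, seed) triple
reproduces trajectories bit for bit, independently of the C++ standard
library. Neighbour search uses cell lists rebuilt every step (correctness
over speed), with a brute-force all-pairs path kept as a cross-check;
boxes too small for three cells per axis fall back to brute force
automatically.

## 3. Mesophase diagnostics

* `density_field()` deposits one species onto a voxel grid with
  cloud-in-cell weights under periodic boundaries; deposition conserves
  mass to machine precision. The default 32³ grid on a 20³ box (voxel
  ≈ 0.63 $r_c$) resolves the 4–6 $r_c$ lamellar period without noise
  domination.
* `isodensity_surface()` triangulates a density level by marching
  tetrahedra (6 tetrahedra per cube) with open boundaries at the box
  faces; the default level is the species mean. On a Gaussian blob the
  half-maximum surface area agrees with the analytic sphere to well
  within 5%.
* `structure_factor()` evaluates $S(q) = |\sum_j e^{iq\cdot r_j}|^2/N$ on
  the lattice-commensurate wavevectors of the periodic box, radially
  binned; it reports both the binned peak and the exact strongest mode.
  Lamellar order appears as a dominant low-$q$ peak (hand-built slabs of
  period 5 in a 20-box peak at $q_1 = 2\pi/5$ with odd harmonics, the
  square-wave signature). Experimental SAXS ratios are deliberately not
  asserted against simulation output: the module reports raw peak
  positions and ratios only.
* `interface_enrichment()` defines the head/water interface as voxels
  where the smoothed densities of both channel species exceed half their
  means (one pass of 7-point neighbour averaging; `width` adds binary
  dilations) and scores a target species by its density ratio inside
  versus everywhere. Ethanol and drug localisation at the channel
  interface of the assembled gel shows up as ratios above 1.

## 4. Release and permeation kinetics

Released fraction $M_t/M_\infty$ is fitted by three empirical laws:
zero-order $kt$, Higuchi $kt^{1/2}$ and Ritger–Peppas $kt^n$. The
one-parameter laws are origin-constrained linear least squares in
transformed time; Ritger–Peppas is initialised in log–log space and
refined by Levenberg–Marquardt on the original scale, because a pure
log-space fit over-weights early low-fraction points. The reported
correlation coefficient $r$ is the Pearson correlation between observed
and fitted fractions (the conventional reporting choice where the
definition is otherwise unspecified). `select_model()` ranks by $r$ with
ties (to 1e-9) broken toward fewer parameters.

Franz-cell bookkeeping: sampled receptor concentrations become cumulative
amounts via $Q_n = C_n V_r + V_s \sum_{i<n} C_i$ (defaults: 15 ml
receptor, 1 ml replaced sample, 0.5 cm² area). `steady_state_flux()` fits
the linear portion of $Q(t)$ — auto-detected as the contiguous ≥3-point
window maximising $R^2$, preferring longer and later windows on ties,
with a manual override — and reports both the slope (µg/h) and the
area-normalised flux $J_{ss}$ (µg/cm²/h) plus the lag time
$-b/m$ clipped at zero. The reported reference flux of the gel
(115 ± 48 µg/cm²/h) derives from full replicate curves that are not
published as data; the three printed cumulative points give 275 µg/cm²/h
under the always-divide-by-area convention, which the package documents
but does not present as a reproduction.

## 5. Synthetic data

The generator module stands in for the laboratory measurements:

* `gen_release()` draws model curves with additive Gaussian noise on the
  fractions, clipped to [0, 1.05] — clipping is a deliberate boundary
  distortion and is documented as such. The `reference_gel` preset is the
  Ritger–Peppas curve through the gel's two characteristic points (10%
  at 0.5 h, 67% at 7 h; $n \approx 0.72$, consistent with
  erosion-dominated release).
* `gen_permeation()` produces lag + linear steady-state curves; two
  presets return the reference cumulative-permeation triples verbatim
  (gel and suspension comparator), flagged `provenance = "reference"`.
* `gen_lamellar_config()` builds perfect alternating slabs — the analytic
  oracle for the structure factor.
* `gen_dpd_fixture()` builds A5–B16 amphiphile/water systems with the
  bridged interaction table.

What the generators deliberately do not emulate: replicate-level variance
structure of the laboratory curves (only mean ± SD summaries exist, so
noise SD is a free parameter), autocorrelated measurement error, drug
degradation, and gel erosion dynamics. Passing tests therefore
demonstrate correctness of the estimators under the stated noise model,
not robustness to every real-data pathology.

## 6. Problem sizes and numerical choices

The test suite exercises the engine at desk scale: thermostat checks use
648 beads ($\rho = 3$) for 4,000 steps; the self-assembly property runs
102 amphiphile chains + 1,268 water beads ($\rho = 3.41$) in a 10³ box
for 20,000 steps across five seeds, asserting a dominant low-$q$
structure-factor peak (≥5× the high-$q$ plateau) for the tail beads in at
least four of five — the scaled-down analogue of the bi-continuous
channel morphology of the full 27,302-bead reference system. These sizes
were chosen as the smallest at which the assembly signal is unambiguous.

Other numerical choices: interaction tables validate symmetry and zero
diagonals at 1e-12; beads closer than 1e-12 exert no pair force (the soft
potential's direction is undefined at contact); tie-breaks in model
selection and window detection are documented above; degenerate inputs
(empty systems, constant fields, windows with zero time span,
non-positive fractions under log fits) raise typed validation errors
naming the offending quantity.

## 7. Known limitations

* No electrostatics, angle/dihedral potentials or pressure coupling; the
  engine is deliberately minimal Groot–Warren DPD.
* Iso-surfaces are not stitched across periodic faces; areas of
  structures crossing the boundary are reported per box image.
* The Ritger–Peppas exponent is only identifiable over a reasonable
  fraction range; profiles clipped at the boundaries bias it.
* Atomistic inputs ($\delta$, cohesive-energy densities) are consumed as
  given; the package does not recompute them, and molecular docking is
  out of scope.
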