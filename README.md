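# pepccs

Collision cross sections and structure assignment for gas-phase peptide
ions.

## What this package is for

Ion-mobility mass spectrometry (IM-MS) separates peptide ions by their
rotationally averaged collision cross section (CCS, Ω, in Å²): extended
conformers collide with the drift gas more often than compact ones, so a
measured arrival time carries structural information. Assigning an
actual three-dimensional structure to a measured CCS requires the other
direction: computing theoretical CCS values for candidate conformers —
typically DFT-optimized geometries with atomic partial charges — and
asking which candidates agree with the experiment.

`pepccs` implements the computational core of that workflow for users
who already have conformer geometries, energies and charges (from any
QM or force-field engine) and want to go from there to an assignable,
Boltzmann-weighted ensemble CCS and an accuracy assessment:

* **Mobility conversions** — the low-field Mason–Schamp relation between
  arrival time and CCS,

  Ω = (3 z e / 16 N) · √(2π / μ k_B T) · 1/K,  K = L / (t_A E),

  with μ the ion–gas reduced mass and N the drift-gas number density.
* **CCS engines** — a trajectory-method (TM) engine that integrates
  classical gas-atom scattering trajectories in the full interaction
  potential (per-atom 12-6 Lennard-Jones plus the ion-induced-dipole
  term −(α/2)|E|², with E the Coulomb field of the partial charges) and
  averages the momentum-transfer integrand (1 − cos χ) over thermal
  speeds, orientations and impact parameters; and a cheap
  projection-approximation (PA) shadow-area engine used as a geometric
  reference. N₂ and He drift gases are parameterized.
* **Ensemble reduction** — all-pairs Kabsch RMSD, modularity-based
  clustering of a conformer ensemble into structural families with
  centroid extraction, and Boltzmann weighting
  w_i ∝ exp(−ΔE_i / k_B T) over conformers within an inclusive
  3 kcal/mol window of the energy minimum.
* **Assessment** — percent CCS error, success classification at the 3%
  threshold, per-method aggregates, selection of the better of two
  dispersion-correction variants per peptide, and the N-to-C-terminal
  distance compactness metric; a packaged reference table carries
  experimental and computed CCS values for 23 tryptic peptides
  (3–14 residues, [M + H]⁺, N₂ drift gas) at five DFT levels.
* **Synthetic fixtures** — deterministic generators (ideal polyglycine
  chains, toy ions, planted clustered ensembles) so the entire pipeline
  runs and is testable offline.

File formats: extended XYZ with an optional fifth partial-charge column
("xyzq") and a delimited ensemble manifest (`file, energy, unit`).

## Worked example

```r
library(pepccs)

## Evaluate a DFT method against the packaged experimental reference
evaluate_reference("table1", method = "D3(0)-B3LYP/6-31G(d)")
#> <evaluation_summary> D3(0)-B3LYP/6-31G(d): mean |error| 3.7% +/- 3, 12/23 within 3.0%

## Per-peptide best of the two dispersion damping variants
evaluate_reference("table2", best_of = c("D3(0)-B3LYP/6-31G(d,p)",
                                         "D3(BJ)-B3LYP/6-31G(d,p)"))
#> <evaluation_summary> best of {D3(0)-B3LYP/6-31G(d,p), D3(BJ)-B3LYP/6-31G(d,p)}: mean |error| 2.1% +/- 1, 17/23 within 3.0%

## Trajectory-method CCS of a synthetic protonated hexaglycine in N2
g   <- build_polyglycine(6)              # 46 atoms, net charge +1 e
gas <- buffer_gas("N2")
cfg <- trajectory_config(n_cycles = 4, n_velocity_points = 10,
                         n_mc_per_cycle = 200, seed = 1)
ccs_trajectory_method(g, gas, cfg)
#> <ccs_result> TM: 204.49 +/- 14.39 A^2 (seed 1)

## Boltzmann weights under the inclusive 3 kcal/mol window
bw <- boltzmann_weights(c(0, 0.8, 2.1, 4.9), window = 3)
bw$weights
#> 0.7765 0.2011 0.0224    # the 4.9 kcal/mol conformer is excluded
```

The evaluation summary reads: at the D3(0)-B3LYP/6-31G(d) level the
mean absolute CCS error over the 23 reference peptides is 3.7% (sample
SD ≈ 3), and 12 of 23 predictions fall within the 3% success threshold.
The TM result is the Monte-Carlo collision integral with its
between-cycle standard error; identical seeds reproduce it bit for bit.
An end-to-end run (manifest → clustering → per-conformer TM →
Boltzmann-weighted ensemble CCS) is available as `run_pipeline()`, and
`inst/cli/pepccs.R` exposes `compute`, `ensemble`, `evaluate`,
`fixtures` and `pipeline` subcommands for shell use.

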