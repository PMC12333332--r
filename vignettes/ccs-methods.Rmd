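---
title: "Methods: collision cross sections for gas-phase peptide ions"
author: "pepccs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collision cross sections for gas-phase peptide ions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepccs)
```

# The problem

Ion-mobility mass spectrometry (IM-MS) measures how quickly a peptide
ion drifts through a buffer gas under a weak electric field. The drift
velocity is set by the ion's mobility $K = v_d/E$, and in the low-field
regime the mobility maps onto a single structural observable, the
rotationally averaged collision cross section (CCS, $\Omega$, Å²).
Assigning a three-dimensional conformation to a measured CCS requires
computing theoretical CCS values for candidate structures — geometries
with atomic partial charges, usually from DFT — and comparing them with
experiment under an agreed error budget. `pepccs` implements that
downstream computational chain: mobility conversions, two CCS engines,
conformer-ensemble reduction, Boltzmann-weighted ensemble CCS, and the
evaluation statistics for a packaged 23-peptide experimental reference
set. Everything upstream of a geometry/energy/charge file (structure
prediction, conformer generation, QM optimization) is out of scope; the
package consumes those outputs as files.

# Mobility conversions

The low-field relation used throughout is

$$\Omega \;=\; \frac{3 z e}{16 N}\sqrt{\frac{2\pi}{\mu k_B T}}\;
\frac{1}{K}, \qquad K = \frac{L}{t_A E},$$

with $z$ the charge state, $\mu = m_i m_b/(m_i+m_b)$ the ion–gas
reduced mass, and $N$ the buffer-gas number density. $N$ is derived
from pressure and temperature by the ideal-gas law unless supplied
explicitly, which makes the expression algebraically identical to the
common arrival-time form written with reduced mobility
($K_0 = K\,\frac{P}{760}\frac{273.15}{T}$) and the STP number density —
the two standardization factors are absorbed exactly. The unit tests
check this equivalence against an independently written evaluation of
the reduced-mobility chain, and check roundtrip inversion to $10^{-10}$
relative over random instrument conditions.

# The interaction potential

A buffer-gas particle at position $\mathbf{p}$ near a frozen ion feels

$$V(\mathbf{p}) \;=\; \sum_a \varepsilon_a\!\left[
\left(\tfrac{r_{\min,a}}{r_a}\right)^{12} -
2\left(\tfrac{r_{\min,a}}{r_a}\right)^{6}\right]
\;-\; \frac{\alpha}{2}\,k_c\left|\sum_a q_a
\frac{\hat{\mathbf r}_a}{r_a^{2}}\right|^{2},$$

the per-atom 12-6 Lennard-Jones terms plus the charge-induced-dipole
attraction between the ion's partial charges and the polarizable gas.
Units are Å, kcal/mol, e and Da, with the Coulomb constant
$k_c = 332.0637$ kcal·Å/(mol·e²) — the force-field convention. The
gradient is analytic and is verified against central finite differences
to $10^{-5}$ relative.

Both drift gases are modelled as single isotropic pseudo-atoms. The
per-element $(\varepsilon, r_{\min})$ parameters ship in a versioned
CSV (`inst/extdata/gas_params.csv`) and follow the published
trajectory-method parameterization lineage for N₂ (per-element
$\varepsilon/\sigma$ values tuned against drift-tube data, converted to
$r_{\min} = 2^{1/6}\sigma$) and the original trajectory-method He set.
N₂'s polarizability is 1.710 Å³ and He's 0.205 Å³. The single-site N₂
model omits the diatomic anisotropy and the ion–quadrupole term;
absolute CCS values therefore deviate from codes that include them (and
from the values in the packaged reference tables, which were produced
by such a code on the authors' DFT structures). All engine tests are
property-based for exactly this reason: desk-scale inputs cannot
reproduce the reference absolute values, but they can verify the
physics of the implementation against independent oracles.

# The trajectory-method engine

The TM computes the temperature-averaged momentum-transfer collision
integral

$$\Omega^{(1,1)}(T) = \frac{\int_0^\infty g^5 e^{-\mu g^2/2k_BT}
Q^{(1)}(g)\,dg}{\int_0^\infty g^5 e^{-\mu g^2/2k_BT}\,dg},
\qquad
Q^{(1)}(g) = 2\pi\!\int_0^{b_{\max}} (1-\cos\chi(b,g))\,b\,db,$$

with $\chi$ the classical deflection angle of a gas pseudo-atom of
reduced mass $\mu$ scattering off the frozen, randomly oriented ion.
The reduced mass is used both in the Maxwell–Boltzmann weight and in
the trajectory dynamics (for peptide-sized ions $\mu \approx m_b$, so
the distinction is minor, but it is the kinetically consistent choice).

Numerical choices, in the order they matter:

* **Speed quadrature.** Gauss–Legendre nodes on the reduced speed
  $\gamma = g\sqrt{\mu/2k_BT}$ over $[0.25, 4]$, with the analytic
  weight $\gamma^5 e^{-\gamma^2}$ folded into the integrand and
  normalized by the same quadrature. The excluded tails carry about
  $10^{-4}$ of the total weight. Cutting $\gamma < 0.25$ matters for
  charged ions: at collision energies far below the attractive well the
  gas is captured, trajectories orbit, and the impact-parameter range
  needed for convergence diverges — at negligible weight. The default
  20 nodes mirror common production settings.
* **Maximum impact parameter.** Found per velocity node as the smallest
  $b$ where $|\chi| < 10^{-3}$ rad over a fixed set of probe
  orientations, by a doubling search refined with bisection. A per-node
  $b_{\max}$ (rather than one global value at the slowest speed) keeps
  the Monte-Carlo variance bounded: the slow nodes genuinely need a
  much larger range than the thermal bulk.
* **Sampling.** Orientations are uniform random rotations (Shoemake
  quaternions). Impact parameters are area-uniform and stratified: one
  draw per equal annulus of $b^2$ with a random within-stratum offset.
  Stratification is unbiased and reduces the single-site standard error
  by roughly two orders of magnitude at identical cost. The default
  budget is 10 cycles × 20 velocity nodes × 500 draws; the
  between-cycle scatter yields the reported standard error, which
  scales as $1/\sqrt{n_\mathrm{cycles}}$ (verified by regression over a
  seed ensemble).
* **Integrator.** Adaptive velocity-Verlet: the step is a safety factor
  (`timestep_control`, default 0.05) times the shorter of the
  time-to-nearest-atom at the current speed and the local
  force-curvature time. Each trajectory's total energy drift is checked
  on exit and the step factor is halved (up to four times) until the
  drift is at most $10^{-4}$ relative. Trajectories that fail to exit
  within the step budget are flagged as orbiting and enter the
  integrand with $\chi = \pi$; a result with more than 1% orbiting
  trajectories carries a warning in its provenance.
* **Seeding.** All engine randomness comes from a dedicated
  splitmix64-based generator, independent of R's RNG. The master seed
  expands into per-cycle streams, so increasing `n_cycles` leaves
  earlier cycles unchanged, and identical seeds give bit-identical
  results on any platform. The `n_rotations` budget (default 1000, the
  conventional setting) bounds the orientation set of the
  $b_{\max}$ search; the collision integral itself draws fresh
  orientations per trajectory, which supersedes a separate fixed-grid
  potential average.

The engine is validated against an independent implementation of the
classical central-force deflection integral (turning point by root
bracketing, then 1-D quadrature with the $\sqrt{\cdot}$ singularity
removed): single deflection angles agree to $10^{-3}$ rad, and the
temperature-averaged single-site CCS agrees to well under 1%. A second
oracle checks the steep-core limit: with the attraction scaled to
$10^{-3} k_BT$ the $r^{-12}$ wall scatters like a hard sphere whose
effective radius follows in closed form from the inverse-power
deflection integral, $Q = C_{12}\,\pi (A/E)^{1/6}$ with
$C_{12} \approx 1.046$; the naive turning-point radius would be off by
that same 4.6%, which is a statement about the radius definition, not
the engine.

# The projection approximation

The PA engine is a geometric reference, not the headline method: the
orientation-averaged area of the union of per-atom discs, sampled by
Monte Carlo over uniform orientations. The collision radius of an atom
is $r_{\min}(\mathrm{element},\mathrm{gas})/2$ plus a gas half-radius
taken as half the smallest pair $r_{\min}$ in the gas table (1.336 Å
for both gases). It ignores attraction entirely, so the TM exceeds it
on charged or multi-atom fixtures where the induced-dipole and LJ wells
matter; for a lone neutral atom at high reduced temperature the soft
$r^{-12}$ core makes the TM fall below this generously-radiused shadow
— the expected behaviour, exercised in the tests.

# Ensemble reduction and Boltzmann weighting

Conformer similarity is the minimum RMSD over rigid superpositions
(Kabsch, proper rotations only), computed over heavy atoms by default
because hydrogen positions are the most basis-set-sensitive part of a
QM geometry. The all-pairs RMSD matrix becomes an affinity graph with a
locally scaled Gaussian kernel — each conformer's width is its
7th-nearest-neighbour RMSD — partitioned by Louvain modularity
community detection. Local scaling is the load-bearing choice: with
15–25 structural families the global median pairwise RMSD is dominated
by between-family distances, a global kernel over-connects the graph,
and families merge; the nearest-neighbour scale tracks the within-basin
spread instead. On planted-structure synthetic ensembles the default
recovers the generating partition exactly (60 conformers/3 clusters
across 20 seeds; 1000 conformers with 14–25 planted families reduce to
the same 14–25 centers). A plain average-linkage threshold/medoid mode
is available as a fallback for data without modular structure. Each
cluster is represented by its centroid, the member minimizing summed
RMSD to its cluster.

Ensemble CCS values are Boltzmann-weighted averages over conformers
within an energy window of the minimum:

$$w_i = \frac{e^{-\Delta E_i/k_BT}}{\sum_{j:\,\Delta E_j \le W}
e^{-\Delta E_j/k_BT}}, \qquad
\Omega_\mathrm{ens} = \sum_i w_i\,\Omega_i ,$$

with the window $W = 3$ kcal/mol **inclusive** at the boundary and
$T = 298$ K by default ($k_BT = 0.59219$ kcal/mol). The weighting
temperature is configurable; 298 K matches the collision-integral
temperature and is the natural default when no separate weighting
temperature is stated. Energies are electronic only — no zero-point or
thermal corrections — matching how relative conformer energies are
typically reported in this workflow. Monte-Carlo errors propagate as
$\sqrt{\sum w_i^2\,\mathrm{se}_i^2}$. Where a peptide has several
protonation variants, each protomer should be treated as a separate
ensemble and the protomer containing the global energy minimum carried
forward; the manifest format is agnostic to which geometry generation
produced the conformers.

# Assessment conventions

Percent errors are always computed from raw CCS columns,
$100\,|\Omega_\mathrm{calc}-\Omega_\mathrm{exp}|/\Omega_\mathrm{exp}$,
never from re-read rounded values; rounding to one decimal happens only
at presentation. Success at the 3% threshold is inclusive and judged on
the error at that reported 0.1% precision — a raw 3.01% prints as 3.0%
and counts as a success. This convention is what makes the packaged
reference counts internally consistent (one peptide in the best-variant
column sits at exactly that boundary). The standard deviation of the
per-peptide errors is the sample (n−1) form, configurable to the
population form; the packaged aggregates cannot discriminate between
the two at their printed precision. One cell of the packaged table
(AWSVAR, uncorrected column) carries a printed per-peptide error that
is inconsistent with its own raw CCS columns; the package reports the
recomputed value (13.4%), and the tests pin this discrepancy down
explicitly. Variant selection (`select_best_variant`) takes the smaller
absolute error, with ties going to the first-listed variant — no ties
occur in the packaged data; the rule exists for completeness.

The N-to-C-terminal distance (`n_to_c_distance`) is a plain Euclidean
distance between two caller-chosen reference atoms — conventionally the
N-terminal amine nitrogen and the C-terminal Cα — used as a compactness
proxy; the atom indices are explicit arguments because terminus
conventions differ between pipelines.

# Synthetic fixtures: what they do and do not show

The generators exist so that every stage is exercisable offline and
deterministically:

* `build_polyglycine()` builds glycine homopolymers from standard bond
  lengths and angles with extended (φ = ψ = 180°) or helical
  (φ = −57°, ψ = −47°) backbones. Protonation adds the N-terminal
  proton and smears the +1 formal charge over the ammonium group (+0.4
  on N, +0.2 per H) — a documented toy scheme, deliberately not a
  Mulliken surrogate.
* `make_toy_ion()` provides single sites, rigid dimers and charged
  dipole probes with exactly known coordinates — the oracle targets for
  the engines.
* `make_clustered_ensemble()` plants `k` template chains with mutual
  RMSD at least the requested separation and jitters members with a
  coordinate noise calibrated (including the ~7 degrees of freedom
  removed by superposition) so the measured within-cluster RMSD matches
  the declared spread within 10%.

These fixtures emulate the *statistical shape* of a reduced conformer
ensemble — separated structural families, an energy landscape with
basins, realistic atom counts — but not real conformational sampling,
real charge distributions, or the correlated geometry changes a QM
optimizer produces. Passing tests therefore demonstrate that the
machinery (clustering, weighting, engines, plumbing) behaves correctly,
not that any particular chemistry is reproduced; absolute agreement
with experimental peptide CCS values additionally requires the upstream
conformer generation and QM stages this package deliberately does not
contain.

# Problem sizes and costs

The shipped test-suite and acceptance-script sizes are chosen to give
tight statistical margins at interactive cost: the single-site
TM-vs-oracle comparison runs 600k trajectories (standard error about
0.01% after stratification), the hard-sphere limit 320k, planted-
partition recovery 20 seeds of 60 conformers, and the ensemble
reduction check one 1000-conformer/40-atom ensemble (about half a
million Kabsch superpositions, a few seconds in compiled code). A full
production TM run on a 50-atom charged peptide at the default
10×20×500 budget takes on the order of a minute per conformer on one
core; the between-cycle standard error tells you directly whether more
cycles are warranted.

# Known limitations

* Single-site N₂ without the quadrupole term: absolute N₂ CCS values
  are systematically offset relative to diatomic-model codes; rankings
  and sensitivities are preserved.
* Charged, strongly aspherical ions have larger Monte-Carlo variance
  (the induced-dipole tail stretches the impact-parameter range at slow
  nodes); raise `n_mc_per_cycle` or `n_cycles` as the standard error
  indicates.
* The modularity clustering default assumes the ensemble has structural
  families; for featureless clouds use the threshold mode.
* No high-field mobility, no diffuse/inelastic scattering, no quantum
  corrections, no EHSS engine.

# Command-line use

`inst/cli/pepccs.R` is a thin Rscript over the package functions with
`compute`, `ensemble`, `evaluate`, `fixtures` and `pipeline`
subcommands; flags override defaults, and every result record embeds
the full configuration and a hash of it, so a published run can be
reproduced from its own output.
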