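---
title: "Methods: reconstructing GPCR activation with a2amsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing GPCR activation with a2amsm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(a2amsm)
```

## The scientific problem

Class-A G-protein coupled receptors such as the adenosine A2A receptor
activate through an ordered sequence of structural changes: the
TM3–TM6 "ionic lock" salt bridge (R3.50–E6.30) breaks as TM6 swings
outward, and the conserved NPxxY tyrosine Y7.53 on TM7 rotates inward.
Two scalar descriptors therefore summarise activation remarkably well:

* the distance between the R3.50 and E6.30 residue centres of mass
  (~2 Å when the lock is formed, up to ~12 Å in G-protein-competent
  conformations), and
* the heavy-atom RMSD of Y7.53 from its inactive position, after
  superposing the receptor core.

`a2amsm` implements the complete analysis stack that turns trajectory
data in this descriptor plane into a kinetic picture of activation:
k-means discretisation, reversible Markov state model (MSM)
estimation, PCCA+ coarse-graining into macrostates, transition path
theory (TPT) pathway decomposition, goal-oriented adaptive sampling,
and cholesterol occupancy free-energy mapping. Because the original
microsecond-scale MD data are not publicly deposited, the package also
ships calibrated synthetic generators that emulate the statistical
structure of the published landscape, so every stage is testable
end to end on a desk machine.

## The reference landscape

The apo-A2A landscape is represented by six metastable basins in the
(lock distance, Y7.53 RMSD) plane, labelled M0–M5 in order of
increasing equilibrium population:

```{r}
reference_landscape()$basins
```

Basin centres follow the descriptor values reported for each
macrostate: the ionic lock is formed (~2–2.5 Å) in M0 and M1, broken
at 6–8.5 Å in M4 and M5 (we use the range midpoints), 9.5–11 Å in M3
and reaching 12 Å in M2; the RMSD coordinate is low in the
inactive-like states (M0, M4, M3) and high where TM7 has rotated
(M1, M5, M2). Centres not explicitly tabulated in the literature are
placed at the midpoints of the reported ranges — they are documented
estimates, not published coordinates. Basin target weights are the
reported equilibrium populations (0.6, 1.2, 9.9, 17.8, 31.9, 38.4%,
renormalised because the printed values sum to 99.8%).

Each basin is a bivariate Gaussian with a broad co-centred "halo"
(30% of the basin mass, three times the core width). The halos
overlap and create the finite barriers through which basins exchange;
without them a Gaussian-mixture landscape would be effectively
non-ergodic on any simulable timescale. The potential is
$U(x) = -k_BT\,\ln p(x)$ with $p$ the mixture density and
$k_BT = 0.5962$ kcal/mol (300 K, the simulation temperature the
analysis assumes throughout), so the Boltzmann density of $U$ is
exactly $p$.

**Calibration.** The population of a basin is the probability mass of
its *cell* — the set of descriptor points nearer to that basin's
centre than to any other in per-axis width-scaled distance. Because
the halos spill mass across cell boundaries, the mixture coefficients
are calibrated against grid quadrature (0.05 Å spacing): cell masses
are linear in the coefficients, so a single 6 × 6 linear solve makes
every cell carry exactly its target mass. `basin_populations()`
exposes the quadrature and serves as the analytic oracle in the
tests.

Basin widths and the halo parameters control the *kinetics* of the
synthetic landscape, and were chosen once so that the six basins are
simultaneously (i) metastable at the MSM lag time and (ii) fast enough
to exchange many times per trajectory. Narrow rare basins (M0, M1)
would otherwise either dissolve into the background (no spectral gap
at six states) or be visited too rarely for their 0.6% and 1.2%
populations to be estimable from a fixed trajectory budget. With the
shipped geometry the implied-timescale spectrum of a typical campaign
shows five slow exchange processes clearly separated from the fast
intra-basin modes, which is exactly the premise of a six-macrostate
model.

## Langevin sampling

`sample_langevin()` propagates overdamped Langevin dynamics with a
Metropolis acceptance step (MALA). The Metropolis correction makes the
stationary density *exactly* the Boltzmann density of the landscape
regardless of the time step, removing the usual discretisation bias;
the time step (default `dt = 0.025` in reduced units, RMS step
0.22 Å) is therefore a pure speed/acceptance trade-off rather than an
accuracy knob. Trajectories start from independent exact equilibrium
draws of the mixture, so every frame is a correlated equilibrium
sample and occupancy estimators are unbiased at any trajectory
length. Proposals that would take a descriptor negative are rejected
(both descriptors are distances). All generators are bit-reproducible
under a fixed seed.

## MSM estimation and coarse-graining

`cluster_features()` implements mini-batch k-means with k-means++
initialisation (k = 100 for synthetic data; the published analysis
used 890 clusters on two descriptors, a density we do not need at
synthetic scale). `count_matrix()` uses sliding-window counts — the
field standard, maximising data use — and never counts across
trajectory boundaries. `estimate_msm()` computes the
maximum-likelihood reversible transition matrix by the standard
self-consistent fixed-point iteration (converged at 1e-10 in max
norm), restricted to the largest strongly connected set of the count
graph, because the reversible MLE requires irreducibility; frames
outside that set are excluded from populations.

`pcca_macrostates()` implements PCCA+ on the first *n* right
eigenvectors with the inner-simplex vertex search and crisp argmax
assignment. Macrostate populations are sums of stationary weights over
members. The default lag (10 frames) sits on the implied-timescale
plateau of the synthetic landscape; the published model used a 20 ns
lag against its own frame interval.

Uncertainty is a trajectory-level bootstrap (default 100 resamples)
that reruns counting, estimation and PCCA with the discretisation held
fixed; the published population uncertainties state no method, and a
trajectory bootstrap is the standard choice when trajectories are the
unit of independent information. Macrostates are mapped back to named
basins by greedy nearest-centre assignment of their
stationary-weighted mean positions, closest pair first, so labels are
unique and deterministic.

## Transition path theory

`committor()` solves the discrete committor boundary-value problem;
for the reversible chains used here the backward committor is
$1 - q^+$. `net_flux()` forms the gross reactive flux
$f_{ij} = \pi_i q^-_i T_{ij} q^+_j$ and the net flux
$F = \max(0, f - f^\top)$. `decompose_pathways()` extracts pathways
iteratively: take the A→B path whose minimum-edge (bottleneck) flux is
maximal, subtract that flux along the path, repeat until 99.9% of the
total flux is assigned. Ties are broken by lexicographic path order,
making decompositions deterministic. The published analysis names TPT
but not its flux-splitting rule; bottleneck extraction is the common
choice, and the acceptance checks are set-and-recover against the
calibrated fixture rather than assertions of algorithmic identity.
Pathway percentages are computed on the macrostate-level
coarse-grained network, matching the granularity at which activation
routes are reported. Absolute rates are deliberately not headlined:
with only two descriptors the slowest receptor motions are
under-resolved and the kinetics are qualitative.

## The calibrated six-state chain

`reference_chain()` ships a reversible six-state transition matrix
whose stationary distribution equals the reported populations exactly
(enforced by construction through its symmetric flux parametrisation)
and whose analytic TPT decomposition reproduces the four reported
pathway splits: of the M4→M2 flux, 49.5% via M5 and 47.8% via M3; of
the M5→M2 flux, 68.8% direct and 20.7% through M4 and M3.
`calibrate_chain()` regenerates it: Nelder–Mead least squares over the
fifteen log off-diagonal flux weights, objective evaluated with the
package's own analytic TPT, achieved residual ~2e-7 percentage points
(tolerance 0.5; failure to calibrate is an error, never a silently
degraded fixture). "Via M5" is defined as the percentage on extracted
paths containing M5 and not M3 (symmetrically for M3), and "through M4
and M3" as paths containing both.

## Adaptive sampling

`run_campaign()` emulates goal-oriented adaptive sampling at reduced
scale: epochs of short trajectories, respawned from stored frames
ranked by `mix * goal + (1 - mix) / sqrt(1 + visits)`, where the goal
score rises linearly from the inactive anchors (2 Å, 0 Å) to the
active caps (12 Å, 4 Å) and the exploration term counts visits to a
fixed 0.5 Å descriptor-space grid. The ranking formula is this
package's documented choice — published descriptions give the
descriptor set and the exploration/exploitation coupling, not the
ranking internals — with `mix = 0.5` by default. The dynamics law is
never modified: goal-directed and uniform campaigns differ only in
the initial conditions of new trajectories, which the test suite
asserts bit-for-bit on shared epochs.

## Cholesterol occupancy mapping

`occupancy_grid()` histograms per-frame lipid geometric centres into
1 Å cubic bins after wrapping into the box. `standard_occupancy()` is
the uniform-mixing expectation $N_0 = V_B N_A [C] / \eta_B$; the bulk
concentration entering it is a required input (for synthetic scenes it
defaults to the scene's own particle count over its box volume).
`free_energy_grid()` applies $\Delta G = -k_BT \ln(N/N_0)$. The sign
is deliberate: the convention here makes enrichment favourable
(negative), consistent with retaining hotspots *below* a
−0.22 kcal/mol cutoff; a transform without the minus sign would
assign enriched bins positive energies and contradict that retention
rule. Bins never visited are reported as unobserved (NA) rather than
infinitely unfavourable — finite-sampling honesty.

`find_hotspots()` takes local minima (bins below the cutoff no greater
than all 26 neighbours), merges minima closer than 8 Å by single
linkage (the linkage is this package's choice), sums their
probabilities, recomputes the merged free energy from the summed
probability, places the hotspot at the probability-weighted centroid
and retains only hotspots below the cutoff. Merging is idempotent.
`macrostate_hotspots()` reruns the full pipeline per macrostate and
flags hotspots shared between macrostates by 8 Å proximity.

A practical caveat the tests make explicit: at 1 Å bin size the
−0.22 kcal/mol cutoff corresponds to only 1.446-fold enrichment, so
sparse sampling produces spurious shot-noise hotspots. The synthetic
scenes used in the tests are sampled densely enough (hundreds of
counts per bin) that the noise floor sits well below the cutoff; real
analyses need comparable per-bin statistics.

The scene generator (`sample_cholesterol_scene()`) uses a Metropolis
random walk — exact stationary density, as for the landscape — with
periodic x/y boundaries and reflective z walls, mimicking a bilayer
slab. Site depths are bounded at zero (attractive only).

## Problem sizes and numerical choices

The set-and-recover experiments run at fixed study conditions: 200
trajectories × 10,000 steps for the landscape pipeline (k = 100,
lag 10, 100 bootstrap resamples) and 500 × 2,000 steps for the chain
(lag 1). These sizes make the six populations and four pathway splits
recoverable with standard errors a few times smaller than their
targets' tolerances while keeping a full run within a few minutes on
one core. Convergence tolerances: reversible MLE 1e-10 (max norm,
10,000 sweep cap), detailed-balance assertion 1e-8, landscape
calibration 1e-6 mass residual, chain calibration 0.5 percentage
points. Ties everywhere break deterministically (lowest index /
lexicographic path), so identical seeds give identical artifacts.

## What the synthetic generators do and do not show

The generators reproduce the *statistical* targets of the published
landscape — stationary populations, metastability structure, pathway
flux splits, site-enrichment thermodynamics — not its molecular
physics. Passing tests therefore demonstrate that the analysis stack
(featurization → MSM → PCCA → TPT → hotspot mapping) is correct and
well-calibrated, and that it recovers known ground truth through the
whole pipeline. They do not validate force fields, sampling
completeness of real MD, or the two-descriptor projection itself; on
real trajectories those remain the user's scientific responsibility.

## Known limitations

* PCCA+ uses the inner-simplex construction with crisp argmax; the
  refined optimisation variants can differ on poorly separated
  spectra (a spectral-gap warning is emitted).
* The featurizer reads PDB topologies and DCD or multi-model PDB
  coordinates; XTC is not parsed.
* Committor/flux routines are dense and intended for the
  macrostate-scale networks used here (up to a few hundred states).
* Absolute kinetics from two descriptors are qualitative; the package
  reports flux percentages, not rates.
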