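---
title: "Methods: event-driven peptide dynamics, replica exchange and WHAM in pepDMD"
author: "pepDMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-driven peptide dynamics, replica exchange and WHAM in pepDMD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepDMD)
```

# The model

pepDMD implements discrete (event-driven) molecular dynamics (DMD) for
coarse-grained peptides.  In DMD every pairwise interaction is a
*step-function* of distance: an impenetrable hard core, a sequence of
spherical shells each with a constant energy, and exactly zero energy
beyond the outermost shell.  Because the potential is piecewise constant
there are no forces; particles fly ballistically and the entire dynamics
is a time-ordered sequence of instantaneous two-body events at the
discontinuity radii.  At each event the velocity change is directed
along the inter-particle axis, conserving linear momentum exactly and
conserving total (kinetic + step) energy exactly across well entries
and exits; when the radial kinetic energy cannot climb an energy step
the pair reflects elastically.

## Units

Lengths are in Angstrom, masses in amu, energies in kcal/mol, and
k~B~ = 1 so temperature is in kcal/mol ("reduced units").  With these
choices the implied time unit, A sqrt(amu mol/kcal) which is about
48.9 fs, is the conventional ~50 fs DMD time unit; the production
protocol of 2x10^6 time units therefore corresponds to 100 ns.
Reduced temperatures are converted to Kelvin with the calibration
factor 5.03x10^2 (`reducedToKelvin()`), so T = 0.575 is roughly 290 K
and T = 0.6 roughly 300 K.

## Coarse graining

The bead model is deliberately coarser than the united-atom models used
in production amyloid studies, whose force-field parameter sets are not
publicly printed and cannot be reproduced: each residue contributes a
backbone bead (mass 56 amu, radius 1.9 A at the Calpha position) and,
except for glycine, a sidechain centroid bead with residue-specific
mass, radius and charge.  The interactions are:

* **Bonds** as infinite square wells: consecutive backbone beads at
  3.8 +/- 0.08 A, a loose next-nearest backbone constraint
  (4.4-7.7 A) that preserves local chain stiffness while allowing both
  helical (~5.4 A) and extended (~7.6 A) geometry, and a
  backbone-sidechain bond at 1.6-2.4 A.
* **Sidechain pair wells** standing in for van der Waals attraction plus
  implicit (solvation-like) hydrophobic burial: a Gaussian-profile well
  of depth eps0 + epsH h~i~ h~j~ (defaults 0.20 and 0.45 kcal/mol),
  where h is the Kyte-Doolittle hydropathy rescaled to [0, 1].  The
  continuous profile is discretized into equal-width shells
  (`discretizePotential()`, default 4 steps) by averaging the function
  over each shell; a convergence test verifies that the two-particle
  Boltzmann-average energy under the discretized potential approaches
  the continuous value as the step count grows.
* **Screened electrostatics** between charged sidechains (Asp/Glu -1,
  Lys/Arg +1, His neutral, termini uncharged): the Debye-Hueckel form
  k~e~ q~i~ q~j~ e^(-r/lambda~D~)/(eps~r~ r) with Debye length 10 A,
  relative dielectric 80, Coulomb constant 332.06 kcal A/(mol e^2), and
  a hard cutoff at 30 A where the screened interaction has decayed to
  negligible size.  Charged pairs are discretized with 10 shells out to
  the cutoff.
* **Hydrogen bonds** as a *reaction-like* event between backbone beads
  at sequence separation >= 3 (any separation across chains).  When an
  eligible unbonded pair crosses the reaction radius (6.5 A, the i,i+4
  Calpha distance on an ideal helix is ~6.2 A) inward, an auxiliary
  distance condition is checked — the next backbone bead of the donor
  residue must be within 7.5 A of the acceptor, a one-distance proxy
  for backbone orientation — and on success the pair switches to a
  deeper two-step "bonded" well (depth eps~HB~ = 1.2 kcal/mol), with
  kinetic energy adjusted so total energy is conserved exactly.  The
  reverse (bond-breaking) event is the mirror image: an outward
  crossing of the same radius with sufficient radial kinetic energy
  reverts the pair to the non-bonded potential.  Environment-dependent
  strength modulation is out of scope at this resolution.

Starting structures come from sequence alone: `buildChain()` places
backbone beads on an ideal right-handed alpha helix (rise 1.5 A, 100
degree twist, radius 2.3 A) or a fully extended line at 3.8 A spacing,
with sidechain beads pointing outward.  A user-supplied PDB can be
mapped onto beads through `readPdb()` (CA/CB extraction), but nothing
in the package requires structure downloads.  The insulin monomer
builder links the A- and B-chain Cys7 sidechain beads with a bead-level
disulfide constraint (3.0-6.0 A — the atomistic 1.8-2.5 A S-S range
scaled to sidechain-centroid resolution, a choice the model exposes in
its configuration rather than hides).

# The integrator

Events are kept in a priority queue with *lazy invalidation*: each
scheduled event records the collision counters of its two participants,
and an event popped with stale counters is discarded rather than
executed.  After every executed event only the two participants'
candidate events are recomputed (against all partners — see below).
Ghost collisions implement the Andersen thermostat: each particle
carries an exponential clock (default rate 0.1 per particle per time
unit) and on firing its velocity is redrawn from the Maxwell-Boltzmann
distribution at the target temperature.  Sampling writes frames every
1000 time units by default.

Numerical choices that matter:

* **Projection guard.**  At each event the pair is projected exactly
  onto the discontinuity radius before the impulse is applied, so
  accumulated floating-point drift can never leave a pair on the wrong
  side of a boundary.  Shell membership is tracked as integer state and
  updated only at crossings, never re-derived from noisy distances.
* **Tie-breaking.**  Events at equal times are ordered by particle ids;
  exact ties are measure-zero but the ordering keeps runs bitwise
  deterministic.  All randomness flows through R's RNG, so a single
  `set.seed()` makes every run exactly reproducible.
* **All-pairs prediction.**  Candidate events are computed against all
  partners rather than through cell lists.  The systems this package
  targets are at most a few hundred beads, where the O(N) rescheduling
  cost per event is far below the bookkeeping cost of cell-crossing
  events; cell lists would be dead code at this scale.
* **Verification.**  With the thermostat off the test suite requires
  relative total-energy drift below 10^-6 over more than 10^4 events
  (measured drift is ~10^-14), exact momentum constancy, and tracked
  potential energy equal to an independent recomputation from
  coordinates; with the thermostat on, sampled velocity components must
  pass a Kolmogorov-Smirnov test against the Maxwell-Boltzmann normal
  at alpha = 0.01.

# Replica exchange

`runREX()` runs one replica per ladder temperature (default: 8
temperatures evenly spaced on [0.5, 0.675] reduced units).  Between
engine segments of one exchange period (default 1000 time units),
neighbouring temperature pairs — alternating even/odd pairs per round,
the standard ergodic schedule — attempt a Metropolis swap accepted with
probability min(1, exp[(1/T~i~ - 1/T~j~)(E~i~ - E~j~)]).  Temperatures
(and thermostat targets) move between replicas; configurations never
jump, and velocities are rescaled by sqrt(T~new~/T~old~) on acceptance
so the kinetic energy matches the new bath.  Energy samples are
demultiplexed by temperature for WHAM, discarding the first half of
each temperature series as burn-in — the same later-half convention
used for contact averaging.

`tuneLadder()` starts from even spacing and iteratively rescales the
log-temperature gaps (shrink by 0.7 where a pair's pilot acceptance
falls below the target window, widen by 1.3 above it, endpoints fixed)
until every neighbour pair's acceptance lies in the window (default
0.3-0.7) or an iteration cap is reached, in which case the best ladder
seen is returned with a warning.  On the bundled square-well-dimer toy
the energy fluctuations are so small relative to the ladder spacing
that all acceptances sit near 1; the tuner then correctly reports that
the window's upper edge cannot be met with fixed endpoints — an honest
outcome the tests exercise, and irrelevant to sampling quality (high
acceptance harms nothing on a two-body system).

# WHAM thermodynamics

`solveWham()` iterates the standard weighted-histogram equations on a
common energy grid,

Omega(E) = sum~k~ H~k~(E) / sum~k~ N~k~ exp(f~k~ - E/T~k~),
exp(-f~k~) = sum~E~ Omega(E) exp(-E/T~k~),

with f~1~ anchored at zero, to tolerance 10^-7 on the free energies
(cap 10^5 iterations; the two-level validation problems converge in a
handful).  Bin width follows Freedman-Diaconis on the pooled samples,
with a range/50 fallback for degenerate (discrete) energy
distributions.  Adjacent-temperature histograms must share at least
one occupied bin; a violation aborts with a message naming the gap.
Canonical averages and Cv(T) = (⟨E^2⟩ - ⟨E⟩^2)/T^2 are Boltzmann sums
over Omega(E) computed in log space.  Cv is reported per system; no
per-mole or per-residue normalization is applied, and the convention is
recorded here rather than guessed at.

Transition temperatures are local Cv maxima filtered by topographic
prominence (default 5% of the curve's dynamic range, mirroring visual
peak identification).  `assignTransitions()` labels each peak with the
auxiliary observable — inter-molecular contact count, backbone RMSD,
helix content — whose steepest temperature derivative lies nearest the
peak, the standard way of telling a dissociation peak from an unfolding
peak; a peak with only flat observables is labelled "unassigned".

# Structural analysis

* **Contacts.**  Two residues are in contact when *any* bead pair
  between them is within 5 A.  At bead resolution "any heavy-atom
  pair" necessarily becomes "any bead pair"; this is a documented
  divergence from atomistic practice.  Frequencies average over the
  later half of each run, pooling independent runs with equal frame
  weight.
* **Binding frequency.**  Per-residue partner-binding values are the
  frame-wise union over all partner residues (not the row maximum of
  the map, which would undercount residues that alternate partners);
  the union choice is recorded in the object and dominates every row
  entry by construction.  Homodimer maps are symmetrized by transpose
  averaging.
* **RMSD.**  Kabsch superposition via SVD with the proper-rotation
  determinant correction; verified against an exhaustive rotation-grid
  search and against an independent library implementation.
* **Clustering protocol.**  Pool runs; keep frames at or below the 0.25
  potential-energy quantile (ties included, so the selection is the
  minimal superset — and potential rather than total energy, since the
  thermostat makes kinetic energy uninformative); drop consecutive
  similar frames with a greedy per-run sliding window of 3500 time
  units (midpoint of the conventional 3000-4000 range); cluster the
  survivors by average-linkage agglomerative clustering on the pairwise
  RMSD matrix cut at k = 50; report clusters in descending size order
  with population fractions, each represented by the member minimizing
  summed RMSD to its co-members.
* **Secondary structure.**  A bead-level stand-in for DSSP: backbone
  virtual torsions are computed per residue window; four consecutive
  torsions within +/-40 degrees of the ideal helical value (~50
  degrees) label the spanned residues helix, two consecutive torsions
  in the trans band (|tau| >= 140 degrees, with near-collinear
  geometries assigned 180) label them strand, helix taking precedence;
  everything else is coil.  Chains shorter than four residues are all
  coil.

# Synthetic data and what the tests do (and do not) show

The generator provides every input the pipeline needs without
downloads:

* **Sequence fixtures** — canonical human and rat amylin (37 residues,
  differing at exactly positions 18, 23, 25, 26, 28 and 29) and the
  insulin A/B chains (21 and 30 residues), hard-coded and checksummed.
* **Toy systems with analytic references.**  The square-well dimer
  (hard core 2.5 A, well of depth 1.5 kcal/mol to 4 A, confining wall
  at 8 A, masses 50 amu) is exactly an effective two-level system in
  its relative coordinate, with closed-form well occupancy, mean energy
  and Cv; the defaults put its heat-capacity shoulder near the default
  ladder so replica exchange has something to exchange over.  The
  two-level sampler draws energies directly from the Boltzmann
  distribution with Schottky closed forms.  The harmonic-like chain is
  a bonded stress test.  Every analytic reference is itself verified
  against brute-force quadrature in the tests.
* **Planted trajectories** fabricate frames realizing prescribed
  contact frequencies (4 A vs 8 A placements on an evenly interleaved
  schedule, so any aligned window measures the planted fraction) and
  prescribed rigid conformational groups (intra-group RMSD ~0.05 A,
  inter-group several A).  These frames are *not* dynamical — bonded
  geometry is not maintained — and exist purely to give the analysis
  code inputs with known answers.

Passing tests therefore demonstrate that the integrator is exact, that
the sampling machinery is canonical, and that every analysis operation
returns the provably correct answer on constructed input.  They do
*not* demonstrate force-field realism: peak locations, hotspot residue
identities and cluster populations of real amylin/insulin systems
depend on interaction parameters far richer than this two-bead model,
and quantitative reproduction of such results is explicitly out of
scope.

# Problem sizes

The test suite and the acceptance script run at desk scale by choice:
toy-system replica exchange uses 2x10^4 time units with a 5x10^3 pilot
for ladder tuning; the end-to-end peptide check runs an 8-replica
exchange of a two-chain 10-residue fragment dimer for 10^4 time units;
WHAM validations use 2x10^4 samples per temperature; conservation tests
accumulate >10^4 events.  The production protocol encoded in
`defaultRunConfig()` (2x10^6 time units, 10-20 independent runs) is
what a real study would submit, and nothing in the implementation
depends on the shorter lengths.

# Known limitations

* Two beads per residue cannot express sidechain rotamers, backbone
  hydrogen-bond geometry beyond the one auxiliary distance, or
  environment-dependent hydrogen-bond strengths.
* The hydrophobicity-product well is a stand-in with two free scale
  parameters; it produces sensible association behaviour, not
  transferable thermodynamics.
* Charges are fixed (no pH dependence); termini are uncharged.
* Secondary-structure labels are virtual-torsion bands, not DSSP.
* Sheet topology classification is limited to what contact-map
  diagonals reveal (parallel contacts run along the main diagonal,
  antiparallel across it); no explicit strand-pairing detector is
  provided.
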