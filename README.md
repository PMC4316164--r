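# pepDMD

Event-driven (discrete) molecular dynamics for coarse-grained peptides,
with replica-exchange sampling, WHAM thermodynamics and structural
analysis — an R/Bioconductor-style implementation of the simulation and
analysis protocol used to study peptide folding, dimerization and
hetero-molecular binding (e.g. amylin/IAPP self-association and its
inhibition by insulin binding).

## Who this is for

Researchers who want a fully inspectable, exactly testable DMD pipeline
at desk scale: method developers checking sampling and analysis
machinery against closed-form references, and teachers/students of
molecular simulation.  It is *not* a production force field — the
two-bead-per-residue model ships with a repo-defined parameter table,
and quantitative force-field-dependent results (peak locations for real
peptides, hotspot residue lists, cluster populations) are out of scope.

## What is inside

* **Discrete molecular dynamics** (`runDMD`): pairwise step-function
  potentials; exact event-driven integration via a priority queue with
  lazy invalidation; hard-sphere cores, square-well bonds,
  discretized hydrophobic + Debye–Hückel screened electrostatic wells
  (Debye length 10 Å, cutoff 30 Å); reaction-style backbone hydrogen
  bonding; Andersen thermostat (Maxwell–Boltzmann ghost collisions).
  Velocities update at each collision by conservation of energy and
  momentum:
  `v_r' = sign(v_r) sqrt(v_r² − 2ΔU/μ)` across a step of height ΔU,
  elastic reflection when `½ μ v_r² ≤ ΔU`.
* **Replica exchange** (`runREX`, `tuneLadder`): default 8 replicas on
  T ∈ [0.5, 0.675] (reduced units, k_B = 1; × 5.03 × 10² for Kelvin),
  Metropolis swaps with `p = min(1, exp[(1/T_i − 1/T_j)(E_i − E_j)])`,
  ladder auto-tuning to a 0.3–0.7 acceptance window.
* **WHAM** (`solveWham`, `specificHeat`, `reweightObservable`):
  density of states from multi-temperature histograms,
  `C_v(T) = (⟨E²⟩ − ⟨E⟩²)/T²`, peak detection (`findTransitions`) and
  peak assignment to the steepest observable (`assignTransitions`).
* **Structure analysis**: residue contact-frequency maps (5 Å any-bead
  cutoff, later-half averaging), per-residue binding frequencies,
  Kabsch RMSD, the standard clustering protocol (lowest-energy quarter
  → 3500-t.u. sliding window → 50 average-linkage clusters → min-RMSD
  centroids), bead-level secondary structure.
* **Synthetic data**: hIAPP/rIAPP/insulin sequence fixtures, toy
  systems with analytic thermodynamics (square-well dimer, two-level
  sampler), planted-contact/planted-cluster trajectories.
* **IO/CLI**: FASTA (Biostrings), single- and multi-model PDB with
  B-factor coloring, CSV energy logs, flat config files, and a thin
  `inst/exec/dmd.R` command line (`fixtures`, `build`, `run`, `rex`,
  `thermo`, `contacts`, `cluster`, `toy`).

## Worked example

Replica exchange on the bundled square-well dimer (a system whose
relative coordinate is an exact two-level system, so the heat-capacity
curve has a closed form to compare against):

```r
library(pepDMD)

toy    <- makeToySystem("square_well_dimer", eps = 2.2)
ladder <- replicaLadder()        # 8 replicas on [0.5, 0.675]
rex    <- runREX(toy$system, ladder, duration = 4e4, seed = 42,
                 sampleInterval = 100)
round(acceptanceRatios(rex), 2)
#> 0.500-0.525 0.525-0.550 0.550-0.575 0.575-0.600 0.600-0.625 0.625-0.650
#>        0.95        0.95        1.00        1.00        0.95        1.00
#> 0.650-0.675
#>        0.95

w <- solveWham(energyHistogramSet(energySamples(rex), temperatures(rex)))
w
#> WhamSolution: 8 temperatures, 51 bins, converged after 6 iterations
#> (residual 2.86e-09)

cv    <- specificHeat(w, seq(0.5, 0.675, by = 0.005))
peaks <- findTransitions(cv)
peaks
#>      T       Cv prominence
#> 1 0.62 2.172474 0.05202711
reducedToKelvin(peaks$T)
#> [1] 311.86
```

Every neighbour pair exchanges well above the 0.3 floor, WHAM converges
in a few iterations, and the recovered specific-heat peak at T = 0.62
sits one grid step from the analytic Schottky peak of this toy (0.625).
The same chain — `runREX` → `energySamples` → `solveWham` →
`specificHeat` → `findTransitions` → `assignTransitions` — applies
unchanged to peptide systems built with `buildChain()` /
`assembleSystem()` from the bundled amylin and insulin sequences, and
`contactMap()` / `clusterProtocol()` consume the same trajectories for
interface mapping and conformational clustering.

## Layout

```
R/                  S4 classes, engine surface, REX, WHAM, analysis, IO
src/dmd_engine.cpp  the event-driven integrator core (Rcpp)
inst/exec/dmd.R     command-line entry point
tests/testthat/     unit, property and end-to-end protocol tests
scripts/acceptance.R
vignettes/peptide-dmd-methods.Rmd   model, algorithms, design choices
```
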