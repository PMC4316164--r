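#' @import methods
NULL

AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

#' Peptide sequence
#'
#' A labelled amino-acid sequence (one-letter codes) belonging to one chain.
#'
#' @slot id character label for the peptide.
#' @slot residues character vector of one-letter residue codes.
#' @slot chain single-character chain identifier.
#' @export
setClass("PeptideSequence",
  representation(id = "character", residues = "character", chain = "character"),
  validity = function(object) {
    bad <- which(!(object@residues %in% AA1))
    if (length(object@residues) < 1) return("length >= 1 required")
    if (length(bad))
      return(sprintf("unknown residue code '%s' at position %d",
                     object@residues[bad[1]], bad[1]))
    TRUE
  })

#' Step-function pair potential
#'
#' Piecewise-constant pair energy: an impenetrable hard core at
#' \code{hardCore}, shells between successive \code{radii} with the given
#' \code{energies} (kcal/mol), and exactly zero energy beyond the outermost
#' radius.  When \code{bond} is \code{TRUE} the outermost radius is an
#' infinite outer wall (an infinite square well), used for bonded
#' constraints.
#'
#' @export
setClass("StepPotential",
  representation(hardCore = "numeric", radii = "numeric",
                 energies = "numeric", bond = "logical"),
  validity = function(object) {
    if (object@hardCore <= 0) return("hardCore must be > 0")
    if (length(object@radii) != length(object@energies))
      return("radii and energies lengths differ")
    if (length(object@radii) < 1) return("at least one shell required")
    r <- c(object@hardCore, object@radii)
    if (any(diff(r) <= 0)) return("radii must be strictly increasing and > hardCore")
    if (any(!is.finite(object@energies))) return("energies must be finite")
    TRUE
  })

#' Coarse-grained molecular system
#'
#' Particles (two beads per residue: backbone and sidechain; glycine has no
#' sidechain bead), bonded constraints, and the pairwise step-potential
#' assignment for every non-excluded pair.  Bonded and 1-3 pairs are
#' excluded from non-bonded interactions; backbone pairs at sequence
#' separation >= 3 (or on different chains) additionally carry a
#' reaction-style hydrogen-bond potential they can switch to.
#'
#' @slot particles data.frame with columns id, chain, resIndex, resCode,
#'   role ("backbone"/"sidechain"), mass (amu), radius (Angstrom),
#'   charge (e).
#' @slot coords numeric matrix (N x 3), Angstrom.
#' @slot bonds data.frame with columns i, j (particle ids), dmin, dmax.
#' @slot potentials list of \linkS4class{StepPotential}.
#' @slot pairPot integer matrix, 1-based index into \code{potentials}
#'   (0 = excluded / no interaction).
#' @slot hbPot,hbAux,hbFormed hydrogen-bond machinery: alternative pair
#'   potential index, auxiliary-bead index for the formation condition, and
#'   the current bonded state.
#' @slot forceField parameter list, see \code{\link{defaultForceField}}.
#' @export
setClass("MolecularSystem",
  representation(particles = "data.frame", coords = "matrix",
                 bonds = "data.frame", potentials = "list",
                 pairPot = "matrix", hbPot = "matrix", hbAux = "matrix",
                 hbFormed = "matrix", forceField = "list"),
  validity = function(object) {
    n <- nrow(object@particles)
    if (nrow(object@coords) != n) return("coords/particles mismatch")
    if (any(!is.finite(object@coords))) return("non-finite coordinates")
    if (any(object@particles$mass <= 0)) return("mass must be > 0")
    if (any(object@particles$radius <= 0)) return("radius must be > 0")
    if (!all(dim(object@pairPot) == c(n, n))) return("pairPot must be N x N")
    if (nrow(object@bonds)) {
      bp <- object@pairPot[cbind(object@bonds$i, object@bonds$j)]
      pots <- object@potentials[bp]
      if (any(bp == 0) || !all(vapply(pots, function(p) p@bond, logical(1))))
        return("every bonded pair must be assigned a bond-type potential")
    }
    for (p in object@potentials) {
      v <- validObject(p, test = TRUE)
      if (!isTRUE(v)) return(v)
    }
    TRUE
  })

#' Sampled trajectory of an event-driven run
#'
#' @slot times sampling times (DMD time units; 1 unit is ~50 fs).
#' @slot frames numeric array (nFrames x N x 3) of bead coordinates.
#' @slot epot,ekin per-frame potential / kinetic energy (kcal/mol).
#' @slot temperature per-frame thermostat target (reduced units).
#' @slot runId per-frame run index (pooled trajectories keep provenance).
#' @slot system the \linkS4class{MolecularSystem} simulated.
#' @slot finalCoords,finalVelocities state at the end of the run.
#' @export
setClass("Trajectory",
  representation(times = "numeric", frames = "array", epot = "numeric",
                 ekin = "numeric", temperature = "numeric",
                 runId = "integer", system = "MolecularSystem",
                 sampleInterval = "numeric", finalCoords = "matrix",
                 finalVelocities = "matrix", nEvents = "numeric",
                 velFrames = "array"),
  prototype(velFrames = array(0, c(0, 0, 3))),
  validity = function(object) {
    nf <- length(object@times)
    if (dim(object@frames)[1] != nf) return("frames/times mismatch")
    if (length(object@epot) != nf || length(object@ekin) != nf)
      return("energy series length mismatch")
    TRUE
  })

#' Replica-exchange temperature ladder
#'
#' @slot temperatures strictly increasing reduced temperatures.
#' @slot exchangePeriod time units between swap attempts.
#' @slot attempts,accepts per-neighbor-pair counters.
#' @slot tuned TRUE when produced by \code{\link{tuneLadder}} with all
#'   acceptances inside the target window.
#' @export
setClass("ReplicaLadder",
  representation(temperatures = "numeric", exchangePeriod = "numeric",
                 attempts = "numeric", accepts = "numeric",
                 tuned = "logical"),
  validity = function(object) {
    if (any(diff(object@temperatures) <= 0))
      return("temperatures must be strictly increasing")
    if (any(object@temperatures <= 0)) return("temperatures must be > 0")
    np <- length(object@temperatures) - 1L
    if (length(object@attempts) != np || length(object@accepts) != np)
      return("counter length must be n_replicas - 1")
    if (any(object@accepts > object@attempts))
      return("accepted cannot exceed attempted")
    TRUE
  })

#' Result of a replica-exchange run
#' @export
setClass("RexRun",
  representation(trajectories = "list", ladder = "ReplicaLadder",
                 exchangeLog = "data.frame", samplesByTemperature = "list"))

#' Multi-temperature energy histogram set (common bins)
#' @export
setClass("EnergyHistogramSet",
  representation(temperatures = "numeric", counts = "matrix",
                 binMid = "numeric", binWidth = "numeric",
                 nSamples = "numeric"),
  validity = function(object) {
    if (ncol(object@counts) != length(object@temperatures))
      return("counts columns must match temperatures")
    if (nrow(object@counts) != length(object@binMid))
      return("counts rows must match bins")
    if (any(object@nSamples < 1)) return("every temperature needs >= 1 sample")
    TRUE
  })

#' WHAM solution: dimensionless free energies and density of states
#' @export
setClass("WhamSolution",
  representation(f = "numeric", logOmega = "numeric", binMid = "numeric",
                 binWidth = "numeric", temperatures = "numeric",
                 tol = "numeric", iterations = "numeric",
                 converged = "logical", residual = "numeric"),
  validity = function(object) {
    if (length(object@f) != length(object@temperatures))
      return("one f per temperature required")
    if (abs(object@f[1]) > 1e-12) return("f of first temperature must be 0")
    TRUE
  })

#' Thermodynamic curve on a temperature grid
#'
#' Holds Cv(T) (kcal/(mol K_B), k_B = 1) and any reweighted observables;
#' column \code{Tkelvin} applies the reduced-to-Kelvin scale (5.03e2).
#' @export
setClass("ThermoCurve",
  representation(curve = "data.frame", kelvinScale = "numeric"),
  validity = function(object) {
    if (!all(c("T", "Cv") %in% names(object@curve)))
      return("curve needs columns T and Cv")
    if (any(diff(object@curve$T) <= 0)) return("grid must be strictly increasing")
    if (any(object@curve$Cv < -1e-9)) return("Cv must be non-negative")
    TRUE
  })

#' Residue-pair contact-frequency map
#' @slot freq matrix of contact frequencies in [0, 1]; rows index residues
#'   of \code{rowChain}, columns residues of \code{colChain}.
#' @slot rowBinding,colBinding per-residue any-partner contact frequencies
#'   (frame-wise union, not a row maximum).
#' @export
setClass("ContactMap",
  representation(freq = "matrix", rowChain = "character",
                 colChain = "character", cutoff = "numeric",
                 windowFraction = "numeric", nFrames = "numeric",
                 rowBinding = "numeric", colBinding = "numeric"),
  validity = function(object) {
    if (any(object@freq < -1e-12 | object@freq > 1 + 1e-12))
      return("frequencies must lie in [0, 1]")
    if (length(object@rowBinding) != nrow(object@freq) ||
        length(object@colBinding) != ncol(object@freq))
      return("binding-frequency lengths must match matrix axes")
    TRUE
  })

#' Conformational clustering result
#' @slot assignment cluster id per input frame (1..k, descending size).
#' @slot centroids frame index (into the clustered set) per cluster; each
#'   centroid minimizes the summed RMSD to its co-members.
#' @export
setClass("ClusterSet",
  representation(assignment = "integer", centroids = "integer",
                 sizes = "integer", fractions = "numeric", k = "integer",
                 frameIds = "integer"),
  validity = function(object) {
    if (length(object@sizes) != object@k) return("one size per cluster")
    if (sum(object@sizes) != length(object@assignment))
      return("clusters must partition the frames")
    for (c in seq_len(object@k))
      if (object@assignment[object@centroids[c]] != c)
        return("each centroid must be a member of its cluster")
    TRUE
  })
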