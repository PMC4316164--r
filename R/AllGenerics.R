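# Generics, accessors and show methods.

#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))
#' @export
setGeneric("particleTable", function(x) standardGeneric("particleTable"))
#' @export
setGeneric("coordinates", function(x, ...) standardGeneric("coordinates"))
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @export
setGeneric("potentialEnergies", function(x) standardGeneric("potentialEnergies"))
#' @export
setGeneric("kineticEnergies", function(x) standardGeneric("kineticEnergies"))
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))
#' @export
setGeneric("acceptanceRatios", function(x) standardGeneric("acceptanceRatios"))
#' @export
setGeneric("frequencyMatrix", function(x) standardGeneric("frequencyMatrix"))
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))
#' @export
setGeneric("freeEnergies", function(x) standardGeneric("freeEnergies"))
#' @export
setGeneric("densityOfStates", function(x) standardGeneric("densityOfStates"))
#' @export
setGeneric("thermoTable", function(x) standardGeneric("thermoTable"))

setMethod("nParticles", "MolecularSystem", function(x) nrow(x@particles))
setMethod("particleTable", "MolecularSystem", function(x) x@particles)
setMethod("coordinates", "MolecularSystem", function(x, ...) x@coords)
setMethod("chainIds", "MolecularSystem",
          function(x) unique(x@particles$chain))
setMethod("chainIds", "PeptideSequence", function(x) x@chain)

setMethod("nFrames", "Trajectory", function(x) length(x@times))
setMethod("frameTimes", "Trajectory", function(x) x@times)
setMethod("potentialEnergies", "Trajectory", function(x) x@epot)
setMethod("kineticEnergies", "Trajectory", function(x) x@ekin)
setMethod("coordinates", "Trajectory", function(x, frame = NULL, ...) {
  if (is.null(frame)) return(x@frames)
  matrix(x@frames[frame, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
})

setMethod("temperatures", "ReplicaLadder", function(x) x@temperatures)
setMethod("acceptanceRatios", "ReplicaLadder", function(x) {
  r <- ifelse(x@attempts > 0, x@accepts / x@attempts, NA_real_)
  names(r) <- paste0(format(x@temperatures[-length(x@temperatures)], digits = 4),
                     "-", format(x@temperatures[-1], digits = 4))
  r
})
setMethod("temperatures", "RexRun", function(x) temperatures(x@ladder))
setMethod("acceptanceRatios", "RexRun", function(x) acceptanceRatios(x@ladder))
setMethod("temperatures", "WhamSolution", function(x) x@temperatures)
setMethod("freeEnergies", "WhamSolution", function(x) {
  setNames(x@f, format(x@temperatures, digits = 4))
})
setMethod("densityOfStates", "WhamSolution", function(x) {
  data.frame(E = x@binMid, logOmega = x@logOmega)
})
setMethod("thermoTable", "ThermoCurve", function(x) x@curve)

setMethod("frequencyMatrix", "ContactMap", function(x) x@freq)
setMethod("clusterSizes", "ClusterSet", function(x) x@sizes)
setMethod("clusterCentroids", "ClusterSet", function(x) x@centroids)

setMethod("show", "PeptideSequence", function(object) {
  cat(sprintf("PeptideSequence '%s' (chain %s, %d aa)\n  %s\n",
              object@id, object@chain, length(object@residues),
              paste(object@residues, collapse = "")))
})

setMethod("show", "StepPotential", function(object) {
  cat(sprintf("StepPotential: core %.2f A, %d shell(s) to %.2f A%s\n",
              object@hardCore, length(object@radii), max(object@radii),
              if (object@bond) " (bond wall)" else ""))
  cat("  energies (kcal/mol):",
      paste(sprintf("%.3f", object@energies), collapse = ", "), "\n")
})

setMethod("show", "MolecularSystem", function(object) {
  p <- object@particles
  cat(sprintf("MolecularSystem: %d beads, %d chain(s) [%s], %d bonds, %d potentials\n",
              nrow(p), length(unique(p$chain)),
              paste(unique(p$chain), collapse = ","),
              nrow(object@bonds), length(object@potentials)))
  cat(sprintf("  residues per chain: %s\n",
      paste(vapply(split(p$resIndex, p$chain), function(z) length(unique(z)),
                   integer(1)), collapse = ", ")))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames over %.0f time units (%d beads)\n",
              length(object@times), max(object@times),
              dim(object@frames)[2]))
  cat(sprintf("  <Epot> = %.3f, <Ekin> = %.3f kcal/mol, %g events\n",
              mean(object@epot), mean(object@ekin), object@nEvents))
})

setMethod("show", "ReplicaLadder", function(object) {
  cat(sprintf("ReplicaLadder: %d replicas on [%.4g, %.4g], exchange every %g t.u.%s\n",
              length(object@temperatures), min(object@temperatures),
              max(object@temperatures), object@exchangePeriod,
              if (isTRUE(object@tuned)) " (tuned)" else ""))
  if (any(object@attempts > 0)) {
    cat("  acceptance:",
        paste(sprintf("%.2f", acceptanceRatios(object)), collapse = " "), "\n")
  }
})

setMethod("show", "RexRun", function(object) {
  cat(sprintf("RexRun: %d replicas, %d exchange rounds logged\n",
              length(object@trajectories), nrow(object@exchangeLog)))
  show(object@ladder)
})

setMethod("show", "WhamSolution", function(object) {
  cat(sprintf("WhamSolution: %d temperatures, %d bins, %s after %g iterations (residual %.2e)\n",
              length(object@temperatures), length(object@binMid),
              if (object@converged) "converged" else "NOT converged",
              object@iterations, object@residual))
})

setMethod("show", "ThermoCurve", function(object) {
  cat(sprintf("ThermoCurve on %d grid points, T in [%.3f, %.3f] (x %.0f K)\n",
              nrow(object@curve), min(object@curve$T), max(object@curve$T),
              object@kelvinScale))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap %s x %s: %d x %d residues, cutoff %.1f A, %d frames\n",
              object@rowChain, object@colChain, nrow(object@freq),
              ncol(object@freq), object@cutoff, object@nFrames))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d clusters over %d frames; top sizes: %s\n",
              object@k, length(object@assignment),
              paste(utils::head(object@sizes, 5), collapse = ", ")))
})
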