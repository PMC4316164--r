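# R surface over the event-driven integrator.

.potList <- function(sys) {
  lapply(sys@potentials, function(p)
    list(hardCore = p@hardCore, radii = p@radii, energies = p@energies,
         bond = p@bond))
}

#' Andersen thermostat kick
#'
#' Draw a fresh velocity from the Maxwell-Boltzmann distribution at
#' reduced temperature \code{T} (k_B = 1): each component is normal with
#' variance T/m.  At T = 0 the particle is stopped.
#'
#' @param mass amu (may be a vector; one 3-vector per mass is returned).
#' @param temperature reduced units, >= 0.
#' @return numeric matrix length(mass) x 3.
#' @export
thermostatKick <- function(mass, temperature) {
  if (temperature < 0) stop("negative temperature")
  n <- length(mass)
  matrix(stats::rnorm(3 * n, 0, sqrt(temperature / rep(mass, 3))), n, 3)
}

#' Earliest discontinuity crossing for one pair
#'
#' Solves the ballistic quadratic for the earliest time at which the pair
#' separation crosses the hard core or any shell radius of \code{pot}.
#'
#' @return list(time, radius, dir, kind); time is Inf when the relative
#'   motion never reaches a discontinuity.
#' @export
nextPairEvent <- function(x1, v1, x2, v2, pot) {
  stopifnot(is(pot, "StepPotential"))
  cpp_next_pair_event(as.numeric(x1), as.numeric(v1), as.numeric(x2),
                      as.numeric(v2),
                      list(hardCore = pot@hardCore, radii = pot@radii,
                           energies = pot@energies, bond = pot@bond))
}

#' Resolve a pair event at a discontinuity
#'
#' Velocity change along the inter-particle unit vector only; linear
#' momentum is conserved exactly, and kinetic + step energy is conserved
#' across a well entry/exit.  If the radial kinetic energy cannot climb
#' the energy step \code{dU} (or \code{wall} is TRUE), the radial
#' components are elastically reflected.
#'
#' @export
resolvePairEvent <- function(x1, v1, m1, x2, v2, m2, dU = 0, wall = FALSE) {
  cpp_resolve_pair_event(as.numeric(x1), as.numeric(v1), m1,
                         as.numeric(x2), as.numeric(v2), m2, dU, wall)
}

#' Kinetic and potential energy of a configuration
#'
#' Potential energy sums the step energy of every non-excluded pair at its
#' current separation (using the hydrogen-bond potential for formed
#' pairs); kinetic energy is \code{sum(m v^2) / 2}.
#'
#' @param sys a \linkS4class{MolecularSystem}.
#' @param velocities N x 3 matrix or NULL (kinetic = 0).
#' @param coords optional coordinates overriding the system's.
#' @return list(kinetic, potential) in kcal/mol.
#' @export
totalEnergy <- function(sys, velocities = NULL, coords = NULL) {
  if (is.null(coords)) coords <- sys@coords
  n <- nrow(coords)
  pot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- sys@pairPot[i, j]
    if (sys@hbPot[i, j] > 0 && sys@hbFormed[i, j]) k <- sys@hbPot[i, j]
    if (k == 0) next
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    pot <- pot + stepEnergy(sys@potentials[[k]], r)
  }
  kin <- if (is.null(velocities)) 0 else
    sum(0.5 * sys@particles$mass * rowSums(velocities^2))
  list(kinetic = kin, potential = pot)
}

#' Run event-driven dynamics
#'
#' Executes collision events in time order (priority queue with lazy
#' stale-event invalidation), samples frames every \code{sampleInterval}
#' time units, and optionally couples every particle to an Andersen
#' thermostat through Poisson ghost collisions at \code{ghostRate} per
#' particle per time unit.  With the thermostat off, total energy and
#' momentum are conserved to floating-point accuracy.
#'
#' @param sys a \linkS4class{MolecularSystem}.
#' @param duration time units (1 unit is ~50 fs; production default in
#'   this field is 2e6 units = 100 ns).
#' @param temperature reduced units (kcal/mol, k_B = 1).
#' @param velocities N x 3 start velocities; by default drawn from the
#'   Maxwell-Boltzmann distribution at \code{temperature}.
#' @param seed optional integer; when given, \code{set.seed(seed)} is
#'   called so the run is exactly reproducible.
#' @return a \linkS4class{Trajectory}.
#' @export
runDMD <- function(sys, duration, temperature, thermostat = TRUE,
                   ghostRate = sys@forceField$ghostRate,
                   sampleInterval = sys@forceField$sampleInterval,
                   velocities = NULL, seed = NULL, runId = 1L) {
  stopifnot(is(sys, "MolecularSystem"), duration >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(velocities))
    velocities <- thermostatKick(sys@particles$mass, temperature)
  res <- cpp_run_dmd(sys@coords, velocities, sys@particles$mass,
                     .potList(sys), sys@pairPot, sys@hbPot, sys@hbAux,
                     sys@hbFormed, sys@forceField$auxMax,
                     temperature, ghostRate, thermostat,
                     duration, sampleInterval)
  if (res$minCoreGap < -1e-9)
    stop(sprintf("integrator failure: hard-core overlap (gap %.3g A) at a sample point",
                 res$minCoreGap))
  nf <- length(res$times)
  sysOut <- sys
  sysOut@hbFormed <- res$hbFormed   # carry formed hydrogen bonds forward
  new("Trajectory", times = res$times, frames = res$frames,
      epot = res$epot, ekin = res$ekin,
      temperature = rep(temperature, nf), runId = rep(as.integer(runId), nf),
      system = sysOut, sampleInterval = sampleInterval,
      finalCoords = res$pos, finalVelocities = res$vel,
      nEvents = res$nEvents, velFrames = res$velFrames)
}

# continue a run from a trajectory's final state (used by replica exchange)
.continueDMD <- function(traj, duration, temperature, ghostRate,
                         sampleInterval) {
  sys <- traj@system
  sys@coords <- traj@finalCoords
  runDMD(sys, duration, temperature, thermostat = TRUE,
         ghostRate = ghostRate, sampleInterval = sampleInterval,
         velocities = traj@finalVelocities)
}

#' Concatenate trajectories of the same system
#' @export
poolTrajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1)
  frames <- do.call(abind3, lapply(trajs, function(t) t@frames))
  new("Trajectory",
      times = unlist(lapply(trajs, function(t) t@times)),
      frames = frames,
      epot = unlist(lapply(trajs, function(t) t@epot)),
      ekin = unlist(lapply(trajs, function(t) t@ekin)),
      temperature = unlist(lapply(trajs, function(t) t@temperature)),
      runId = unlist(lapply(seq_along(trajs), function(k)
        rep(as.integer(k), length(trajs[[k]]@times)))),
      system = trajs[[length(trajs)]]@system,  # carries final bonded state
      sampleInterval = trajs[[1]]@sampleInterval,
      finalCoords = trajs[[length(trajs)]]@finalCoords,
      finalVelocities = trajs[[length(trajs)]]@finalVelocities,
      nEvents = sum(vapply(trajs, function(t) t@nEvents, numeric(1))),
      velFrames = do.call(abind3, lapply(trajs, function(t)
        if (dim(t@velFrames)[1] == dim(t@frames)[1]) t@velFrames else
          array(0, dim(t@frames)))))
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  as <- list(...)
  n2 <- dim(as[[1]])[2]; n3 <- dim(as[[1]])[3]
  n1 <- sum(vapply(as, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, c(n1, n2, n3))
  at <- 0
  for (a in as) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}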