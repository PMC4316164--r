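# Temperature replica exchange over the event-driven engine.

#' Construct a replica ladder
#'
#' Default: 8 temperatures evenly spaced on [0.5, 0.675] reduced units,
#' exchange attempts every 1000 time units.
#' @export
replicaLadder <- function(temperatures = seq(0.5, 0.675, length.out = 8),
                          exchangePeriod = 1000) {
  np <- length(temperatures) - 1L
  new("ReplicaLadder", temperatures = as.numeric(temperatures),
      exchangePeriod = exchangePeriod,
      attempts = rep(0, max(np, 0)), accepts = rep(0, max(np, 0)),
      tuned = FALSE)
}

#' Metropolis swap decision for two replicas
#'
#' Accept iff \code{u < min(1, exp((1/Ti - 1/Tj) (Ei - Ej)))}.  A swap of
#' equal energies, or one that moves the higher energy to the higher
#' temperature, is always accepted.
#'
#' @param Ei,Ej potential energies (kcal/mol) of the replicas currently at
#'   \code{Ti} and \code{Tj} (reduced units, \code{Ti < Tj}).
#' @param u uniform(0,1) variate; drawn internally when NULL.
#' @return list(accept, p) with p the acceptance probability.
#' @export
proposeExchange <- function(Ei, Ej, Ti, Tj, u = NULL) {
  if (Ti <= 0 || Tj <= 0) stop("non-positive temperature")
  if (is.null(u)) u <- stats::runif(1)
  p <- min(1, exp((1 / Ti - 1 / Tj) * (Ei - Ej)))
  list(accept = u < p, p = p)
}

#' Run temperature replica exchange
#'
#' Each replica runs the engine between exchange points; at each exchange
#' point neighbouring temperature pairs (alternating even/odd pairs per
#' round) attempt a Metropolis swap of temperatures.  Configurations stay
#' with their replica - only temperature labels (and thermostat targets)
#' move, and velocities are rescaled by \code{sqrt(Tnew/Told)} on an
#' accepted swap.  Energy samples are demultiplexed by temperature for
#' WHAM.
#'
#' @param sys a \linkS4class{MolecularSystem}.
#' @param ladder a \linkS4class{ReplicaLadder}.
#' @param duration total time units (a multiple of the exchange period).
#' @param seed integer seed for all randomness in the run.
#' @return a \linkS4class{RexRun}.
#' @export
runREX <- function(sys, ladder, duration, seed = NULL,
                   ghostRate = sys@forceField$ghostRate,
                   sampleInterval = sys@forceField$sampleInterval) {
  stopifnot(is(ladder, "ReplicaLadder"))
  validObject(ladder)
  if (!is.null(seed)) set.seed(seed)
  temps <- ladder@temperatures
  R <- length(temps)
  period <- min(ladder@exchangePeriod, duration)
  nRounds <- max(1, floor(duration / period))

  # tempOf[r]: index into temps currently held by replica r
  tempOf <- seq_len(R)
  segs <- vector("list", R)            # per-replica trajectory segments
  state <- vector("list", R)
  for (r in seq_len(R)) {
    state[[r]] <- list(sys = sys,
                       vel = thermostatKick(sys@particles$mass, temps[r]))
  }
  attempts <- rep(0, max(R - 1, 0)); accepts <- rep(0, max(R - 1, 0))
  logRows <- list()
  samples <- lapply(seq_len(R), function(k)
    list(t = numeric(0), E = numeric(0)))

  t0 <- 0
  for (round in seq_len(nRounds)) {
    for (r in seq_len(R)) {
      Tk <- temps[tempOf[r]]
      tr <- runDMD(state[[r]]$sys, period, Tk, thermostat = TRUE,
                   ghostRate = ghostRate, sampleInterval = sampleInterval,
                   velocities = state[[r]]$vel, runId = r)
      tr@times <- tr@times + t0
      # drop the duplicated segment-start frame except in the first round
      keep <- if (round == 1) seq_along(tr@times) else -1L
      seg <- tr
      seg@times <- tr@times[keep]; seg@epot <- tr@epot[keep]
      seg@ekin <- tr@ekin[keep]; seg@temperature <- tr@temperature[keep]
      seg@runId <- tr@runId[keep]
      seg@frames <- tr@frames[keep, , , drop = FALSE]
      seg@velFrames <- tr@velFrames[keep, , , drop = FALSE]
      segs[[r]][[round]] <- seg
      k <- tempOf[r]
      samples[[k]]$t <- c(samples[[k]]$t, seg@times)
      samples[[k]]$E <- c(samples[[k]]$E, seg@epot)
      state[[r]]$sys <- tr@system
      state[[r]]$sys@coords <- tr@finalCoords
      state[[r]]$vel <- tr@finalVelocities
      state[[r]]$epot <- tr@epot[length(tr@epot)]
    }
    t0 <- t0 + period

    if (R >= 2 && round < nRounds) {
      start <- if (round %% 2 == 1) 1L else 2L
      pairs <- if (start <= R - 1) seq(start, R - 1, by = 2) else integer(0)
      repOf <- order(tempOf)           # replica currently at temperature k
      for (k in pairs) {
        ri <- repOf[k]; rj <- repOf[k + 1]
        dec <- proposeExchange(state[[ri]]$epot, state[[rj]]$epot,
                               temps[k], temps[k + 1])
        attempts[k] <- attempts[k] + 1
        logRows[[length(logRows) + 1L]] <- data.frame(
          round = round, pair = k, Ti = temps[k], Tj = temps[k + 1],
          Ei = state[[ri]]$epot, Ej = state[[rj]]$epot,
          p = dec$p, accepted = dec$accept)
        if (dec$accept) {
          accepts[k] <- accepts[k] + 1
          tempOf[ri] <- k + 1L; tempOf[rj] <- k
          state[[ri]]$vel <- state[[ri]]$vel * sqrt(temps[k + 1] / temps[k])
          state[[rj]]$vel <- state[[rj]]$vel * sqrt(temps[k] / temps[k + 1])
        }
      }
    }
  }

  lad <- ladder
  lad@attempts <- attempts; lad@accepts <- accepts
  trajs <- lapply(seq_len(R), function(r) {
    tr <- poolTrajectories(segs[[r]])
    tr@runId <- rep(as.integer(r), length(tr@times))  # one continuous run
    tr
  })
  new("RexRun", trajectories = trajs, ladder = lad,
      exchangeLog = if (length(logRows)) do.call(rbind, logRows) else
        data.frame(round = integer(0), pair = integer(0), Ti = numeric(0),
                   Tj = numeric(0), Ei = numeric(0), Ej = numeric(0),
                   p = numeric(0), accepted = logical(0)),
      samplesByTemperature = lapply(samples, function(s)
        data.frame(t = s$t, E = s$E)))
}

#' Demultiplexed energy samples with burn-in
#'
#' Per-temperature potential-energy samples from a replica-exchange run,
#' discarding the first \code{burnIn} fraction of each temperature series
#' (equilibrium averages follow the later-half convention used for
#' contact maps).
#' @export
energySamples <- function(rex, burnIn = 0.5) {
  stopifnot(is(rex, "RexRun"))
  lapply(rex@samplesByTemperature, function(s)
    s$E[s$t > burnIn * max(s$t)])
}

#' Tune a replica ladder to an acceptance window
#'
#' Starting from even spacing on [Tmin, Tmax], runs short pilot
#' replica-exchange simulations and adjusts the interior temperatures by
#' geometric interpolation (gaps in log T shrink where a neighbour pair's
#' acceptance falls below the window and widen where it exceeds it; the
#' end temperatures stay fixed) until every pair's acceptance lies inside
#' \code{window} or \code{maxRounds} pilots have been used.
#'
#' @param window target acceptance interval, default (0.3, 0.7).
#' @return a \linkS4class{ReplicaLadder} with the pilot acceptance
#'   counters; slot \code{tuned} is FALSE when the iteration cap was
#'   reached with some pair still outside the window (returned with a
#'   warning).
#' @export
tuneLadder <- function(sys, Tmin = 0.5, Tmax = 0.675, nReplicas = 8,
                       window = c(0.3, 0.7), pilotDuration = 5000,
                       exchangePeriod = 1000, maxRounds = 5, seed = NULL) {
  stopifnot(Tmin < Tmax, nReplicas >= 2)
  if (!is.null(seed)) set.seed(seed)
  temps <- seq(Tmin, Tmax, length.out = nReplicas)
  lad <- replicaLadder(temps, exchangePeriod)
  best <- NULL; bestOutside <- Inf
  for (round in seq_len(maxRounds)) {
    pilot <- runREX(sys, lad, pilotDuration,
                    sampleInterval = exchangePeriod)
    acc <- acceptanceRatios(pilot)
    lad <- pilot@ladder
    inside <- !is.na(acc) & acc >= window[1] & acc <= window[2]
    if (sum(!inside) <= bestOutside) {
      best <- lad; bestOutside <- sum(!inside)
    }
    if (all(inside)) {
      lad@tuned <- TRUE
      return(lad)
    }
    if (nReplicas == 2) break          # endpoints fixed: nothing to adjust
    gaps <- diff(log(temps))
    scale <- ifelse(is.na(acc), 1,
                    ifelse(acc < window[1], 0.7,
                           ifelse(acc > window[2], 1.3, 1)))
    gaps <- gaps * scale
    logT <- log(Tmin) + c(0, cumsum(gaps)) /
      sum(gaps) * (log(Tmax) - log(Tmin))
    temps <- exp(logT)
    lad <- replicaLadder(temps, exchangePeriod)
  }
  warning("ladder tuning hit the iteration cap; returning best ladder")
  best@tuned <- FALSE
  best
}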