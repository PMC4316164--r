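# Synthetic inputs: sequence fixtures, toy systems with analytic
# thermodynamic references, and trajectories with planted structure.

#' Bundled peptide sequence fixtures
#'
#' Canonical (UniProt-derived, hard-coded) sequences: human amylin
#' (hIAPP, 37 aa), rat amylin (rIAPP, 37 aa, differing from the human
#' variant at exactly 6 positions: 18, 23, 25, 26, 28, 29), and the two
#' insulin chains (A: 21 aa, B: 30 aa), which in the monomer are
#' cross-linked by disulfide bonds (modelled here between the Cys7
#' sidechain beads, see \code{\link{insulinMonomer}}).
#'
#' @return named list of \linkS4class{PeptideSequence}.
#' @export
fixtureSequences <- function() {
  list(
    hIAPP = peptideSequence("hIAPP",
      "KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY", chain = "A"),
    rIAPP = peptideSequence("rIAPP",
      "KCNTATCATQRLANFLVRSSNNLGPVLPPTNVGSNTY", chain = "A"),
    insulinA = peptideSequence("insulinA",
      "GIVEQCCTSICSLYQLENYCN", chain = "A"),
    insulinB = peptideSequence("insulinB",
      "FVNQHLCGSHLVEALYLVCGERGFFYTPKT", chain = "B"))
}

#' Direct sampler for a two-level system
#'
#' States with energies 0 and \code{dE} and degeneracies \code{g0},
#' \code{g1}; upper-level occupancy
#' \code{p1 = g1 exp(-dE/T) / (g0 + g1 exp(-dE/T))}.
#'
#' @return numeric vector of n sampled energies.
#' @export
sampleTwoLevel <- function(n, temperature, dE = 1, g0 = 1, g1 = 1) {
  p1 <- g1 * exp(-dE / temperature) / (g0 + g1 * exp(-dE / temperature))
  dE * (stats::runif(n) < p1)
}

#' Toy systems with analytic thermodynamic references
#'
#' \describe{
#'   \item{two_level}{No particles: a direct Boltzmann sampler over two
#'     levels (energy gap \code{dE}, degeneracies \code{g0}, \code{g1})
#'     with Schottky closed forms for \code{<E>(T)} and \code{Cv(T)}.}
#'   \item{square_well_dimer}{Two beads (mass \code{m}) with hard core
#'     \code{sigma}, an attractive well of depth \code{eps} out to
#'     \code{lambda}, and a confining outer wall at \code{Rwall}.  The
#'     relative coordinate makes this an exact effective two-level
#'     system: the well occupancy is
#'     \code{p(T) = A e^{eps/T} / (A e^{eps/T} + B)} with
#'     \code{A = (lambda^3 - sigma^3)/3}, \code{B = (Rwall^3 -
#'     lambda^3)/3}, giving \code{<E> = -eps p} and
#'     \code{Cv = (eps/T)^2 p (1 - p)}.}
#'   \item{harmonic_like_chain}{\code{nBeads} beads joined by narrow
#'     square-well bonds; an engine stress test with no closed-form
#'     thermodynamics.}
#' }
#'
#' @return list(system, reference) where reference holds functions
#'   \code{Emean(T)}, \code{Cv(T)} (and \code{occupancy(T)} where
#'   defined); system is NULL for the state sampler.
#' @export
makeToySystem <- function(kind = c("square_well_dimer", "two_level",
                                   "harmonic_like_chain"),
                          dE = 1, g0 = 1, g1 = 1,
                          sigma = 2.5, lambda = 4.0, eps = 1.5, Rwall = 8.0,
                          m = 50, nBeads = 5, d0 = 3.8, delta = 0.1) {
  kind <- match.arg(kind)
  if (kind == "two_level") {
    p1 <- function(T) g1 * exp(-dE / T) / (g0 + g1 * exp(-dE / T))
    return(list(system = NULL, reference = list(
      occupancy = p1,
      Emean = function(T) dE * p1(T),
      Cv = function(T) (dE / T)^2 * p1(T) * (1 - p1(T)),
      sampler = function(n, T) sampleTwoLevel(n, T, dE, g0, g1))))
  }
  if (kind == "square_well_dimer") {
    stopifnot(sigma > 0, lambda > sigma, Rwall > lambda, eps > 0)
    A <- (lambda^3 - sigma^3) / 3
    B <- (Rwall^3 - lambda^3) / 3
    p <- function(T) A * exp(eps / T) / (A * exp(eps / T) + B)
    particles <- data.frame(
      id = 1:2, chain = "T", resIndex = 1:2, resCode = "G",
      role = "backbone", mass = m, radius = sigma / 2, charge = 0,
      stringsAsFactors = FALSE)
    coords <- rbind(c(0, 0, 0), c((sigma + lambda) / 2, 0, 0))
    colnames(coords) <- c("x", "y", "z")
    n <- 2L
    sys <- new("MolecularSystem", particles = particles, coords = coords,
               bonds = data.frame(i = integer(0), j = integer(0),
                                  dmin = numeric(0), dmax = numeric(0)),
               potentials = list(stepPotential(sigma, c(lambda, Rwall),
                                               c(-eps, 0), bond = TRUE)),
               pairPot = matrix(c(0L, 1L, 1L, 0L), 2, 2),
               hbPot = matrix(0L, n, n), hbAux = matrix(0L, n, n),
               hbFormed = matrix(FALSE, n, n),
               forceField = defaultForceField())
    return(list(system = sys, reference = list(
      occupancy = p,
      Emean = function(T) -eps * p(T),
      Cv = function(T) (eps / T)^2 * p(T) * (1 - p(T)))))
  }
  # harmonic_like_chain
  particles <- data.frame(
    id = seq_len(nBeads), chain = "H", resIndex = seq_len(nBeads),
    resCode = "G", role = "backbone", mass = m, radius = 1.5, charge = 0,
    stringsAsFactors = FALSE)
  coords <- cbind((seq_len(nBeads) - 1) * d0, 0, 0)
  colnames(coords) <- c("x", "y", "z")
  bonds <- data.frame(i = seq_len(nBeads - 1), j = 2:nBeads,
                      dmin = d0 - delta, dmax = d0 + delta)
  pots <- list(stepPotential(d0 - delta, d0 + delta, 0, bond = TRUE))
  pairPot <- matrix(0L, nBeads, nBeads)
  for (b in seq_len(nrow(bonds))) {
    pairPot[bonds$i[b], bonds$j[b]] <- 1L
    pairPot[bonds$j[b], bonds$i[b]] <- 1L
  }
  sys <- new("MolecularSystem", particles = particles, coords = coords,
             bonds = bonds, potentials = pots, pairPot = pairPot,
             hbPot = matrix(0L, nBeads, nBeads),
             hbAux = matrix(0L, nBeads, nBeads),
             hbFormed = matrix(FALSE, nBeads, nBeads),
             forceField = defaultForceField())
  list(system = sys, reference = list(Emean = NULL, Cv = NULL))
}

#' Trajectory with planted contacts and planted conformational clusters
#'
#' Builds a two-chain poly-glycine stand-in system (chains A and B,
#' backbone beads only) and fabricates frames in which (a) chosen
#' chain-A/chain-B residue pairs are in contact (4 A) in a prescribed
#' fraction of frames (8 A otherwise, evenly interleaved so any aligned
#' window measures the same fraction) and (b) chain A adopts one of a
#' few rigid conformational groups of prescribed sizes (intra-group RMSD
#' below ~0.1 A, inter-group RMSD of several A).  Frames are not
#' dynamical - bonded geometry is not maintained; the object is analysis
#' input only.
#'
#' @param nFrames number of frames; times are 0, 1, ..., nFrames - 1.
#' @param contactPlan data.frame(i, j, freq): chain-A residue, chain-B
#'   residue, target contact frequency in [0, 1].
#' @param clusterPlan integer vector of group sizes (must sum to
#'   nFrames), or NULL.
#' @param seed integer seed (the construction is deterministic for a
#'   fixed seed).
#' @return a \linkS4class{Trajectory}.
#' @export
plantedTrajectory <- function(nFrames, contactPlan = NULL,
                              clusterPlan = NULL, seed = 1, L = 10) {
  set.seed(seed)
  if (!is.null(contactPlan)) {
    if (any(contactPlan$freq < 0 | contactPlan$freq > 1))
      stop("infeasible plan: frequency outside [0, 1]")
    if (anyDuplicated(contactPlan$j))
      stop("infeasible plan: one chain-B residue in several pairs")
    L <- max(L, contactPlan$i, contactPlan$j)
  }
  if (!is.null(clusterPlan) && sum(clusterPlan) != nFrames)
    stop("cluster plan sizes must sum to nFrames")

  seqA <- peptideSequence("plantA", strrep("G", L), chain = "A")
  seqB <- peptideSequence("plantB", strrep("G", L), chain = "B")
  A <- buildChain(seqA, "extended")
  B <- buildChain(seqB, "extended")
  Bcoords <- sweep(B@coords, 2, c(0, 0, 50), "+")
  sys <- assembleSystem(list(A, B), "proximal_parallel", separation = 50)
  sys@coords <- rbind(A@coords, Bcoords)

  baseA <- A@coords
  groupOf <- if (is.null(clusterPlan)) rep(1L, nFrames) else
    rep(seq_along(clusterPlan), clusterPlan)
  groups <- lapply(seq_len(max(groupOf)), function(g)
    baseA + matrix(stats::rnorm(3 * nrow(baseA), 0, 3), ncol = 3))

  frames <- array(NA_real_, c(nFrames, nrow(sys@coords), 3))
  nA <- nrow(baseA)
  for (k in seq_len(nFrames)) {
    Ak <- groups[[groupOf[k]]] +
      matrix(stats::rnorm(3 * nA, 0, 0.02), ncol = 3)
    Bk <- Bcoords
    if (!is.null(contactPlan)) for (r in seq_len(nrow(contactPlan))) {
      active <- floor(k * contactPlan$freq[r]) >
        floor((k - 1) * contactPlan$freq[r])
      d <- if (active) 4 else 8
      Bk[contactPlan$j[r], ] <- Ak[contactPlan$i[r], ] + c(0, 0, d)
    }
    frames[k, , ] <- rbind(Ak, Bk)
  }
  nf <- nFrames
  new("Trajectory", times = as.numeric(seq_len(nf) - 1), frames = frames,
      epot = rep(0, nf), ekin = rep(0, nf), temperature = rep(0, nf),
      runId = rep(1L, nf), system = sys, sampleInterval = 1,
      finalCoords = matrix(frames[nf, , ], ncol = 3),
      finalVelocities = matrix(0, nrow(sys@coords), 3), nEvents = 0)
}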