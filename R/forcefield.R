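# Coarse-grained force field: per-residue bead parameters and the
# construction / discretization of pairwise step potentials.
#
# The model is two beads per residue (backbone + sidechain centroid;
# glycine is backbone-only).  Non-bonded sidechain attraction follows a
# hydrophobicity-scale pairwise well (a stand-in for van der Waals plus
# implicit solvation at this resolution), charged sidechains add a
# Debye-Hueckel screened Coulomb term, and backbone beads carry a
# reaction-style hydrogen-bond potential.  All continuous profiles are
# discretized into step functions before the engine sees them.

# residue masses (Da, residue = amino acid - water), sidechain radii (A)
# and Kyte-Doolittle hydropathy
.aaData <- data.frame(
  code  = c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V"),
  mass  = c(71.08,156.19,114.10,115.09,103.14,128.13,129.12,57.05,137.14,
            113.16,113.16,128.17,131.19,147.18,97.12,87.08,101.10,186.21,
            163.18,99.13),
  scRadius = c(1.40,2.00,1.70,1.65,1.60,1.85,1.80,NA,1.85,1.80,
               1.80,1.95,1.90,1.95,1.70,1.45,1.60,2.10,2.00,1.65),
  kd    = c(1.8,-4.5,-3.5,-3.5,2.5,-3.5,-3.5,-0.4,-3.2,4.5,
            3.8,-3.9,1.9,2.8,-1.6,-0.8,-0.7,-0.9,-1.3,4.2),
  charge = c(0,1,0,-1,0,0,-1,0,0,0, 0,1,0,0,0,0,0,0,0,0),
  stringsAsFactors = FALSE)
rownames(.aaData) <- .aaData$code

#' Construct a step-function pair potential
#'
#' @param hardCore hard-core radius (Angstrom).
#' @param radii strictly increasing shell outer radii, all > hardCore.
#' @param energies shell energies (kcal/mol); energy beyond the outermost
#'   radius is exactly zero.
#' @param bond if TRUE the outermost radius is an infinite outer wall
#'   (infinite square well, used for bonded constraints).
#' @return a \linkS4class{StepPotential}.
#' @export
stepPotential <- function(hardCore, radii, energies = rep(0, length(radii)),
                          bond = FALSE) {
  new("StepPotential", hardCore = as.numeric(hardCore),
      radii = as.numeric(radii), energies = as.numeric(energies),
      bond = isTRUE(bond))
}

#' Evaluate a step potential at distances
#' @export
stepEnergy <- function(pot, r) {
  stopifnot(is(pot, "StepPotential"))
  vapply(r, function(ri) {
    if (ri < pot@hardCore) return(Inf)
    s <- which(ri < pot@radii)
    if (!length(s)) {
      if (pot@bond) Inf else 0
    } else pot@energies[s[1]]
  }, numeric(1))
}

#' Discretize a continuous pair energy into a step potential
#'
#' Shell boundaries partition \code{[hardCore, rMax]} into \code{nSteps}
#' equal-width shells; each step energy is the mean of the continuous
#' function over its shell (1-D average in r).  Energy beyond \code{rMax}
#' is exactly zero.
#'
#' @param continuousEnergy function of distance (Angstrom) returning
#'   kcal/mol, finite on \code{[hardCore, rMax]}.
#' @export
discretizePotential <- function(continuousEnergy, hardCore, rMax, nSteps) {
  if (nSteps < 1) stop("nSteps must be >= 1")
  if (rMax <= hardCore) stop("rMax must exceed hardCore")
  b <- seq(hardCore, rMax, length.out = nSteps + 1)
  e <- vapply(seq_len(nSteps), function(k) {
    stats::integrate(function(r) vapply(r, continuousEnergy, numeric(1)),
                     b[k], b[k + 1], rel.tol = 1e-9)$value / (b[k + 1] - b[k])
  }, numeric(1))
  stepPotential(hardCore, b[-1], e)
}

#' Debye-Hueckel screened Coulomb energy
#'
#' \code{ke q1 q2 exp(-r / lambdaD) / (epsR r)} for \code{r < cutoff},
#' exactly zero at and beyond the cutoff where the screened potential has
#' decayed away.
#'
#' @param q1,q2 charges (elementary-charge units).
#' @param r distance(s), Angstrom; must be > 0.
#' @param params list with \code{lambdaD} (Debye length, default 10 A),
#'   \code{cutoff} (default 30 A), \code{epsR} (relative dielectric, 80)
#'   and \code{ke} (Coulomb constant, 332.06 kcal A / (mol e^2)).
#' @return energy in kcal/mol.
#' @export
screenedCoulomb <- function(q1, q2, r, params = defaultForceField()$electro) {
  if (any(r <= 0)) stop("r must be > 0")
  if (params$cutoff <= params$lambdaD || params$lambdaD <= 0)
    stop("need cutoff > lambdaD > 0")
  u <- params$ke * q1 * q2 * exp(-r / params$lambdaD) / (params$epsR * r)
  u[r >= params$cutoff] <- 0
  u
}

#' Default coarse-grained force-field parameters
#'
#' Energies in kcal/mol, lengths in Angstrom, k_B = 1 so temperatures are
#' in kcal/mol.  Sidechain pair wells have depth
#' \code{eps0 + epsH h_i h_j} with h the Kyte-Doolittle hydropathy
#' rescaled to [0, 1]; charged sidechains (D, E: -1; K, R: +1; H neutral;
#' termini uncharged) add the screened Coulomb term.  Backbone pairs at
#' sequence separation >= 3 (any separation across chains) can react into
#' a hydrogen-bond well of depth \code{epsHB}.
#'
#' @param nSteps discretization steps for the sidechain well (charged
#'   pairs use \code{nStepsElec} shells out to the 30 A cutoff).
#' @export
defaultForceField <- function(nSteps = 4) {
  list(
    bbMass = 56, bbRadius = 1.9,
    eps0 = 0.20, epsH = 0.45, wellOut = 7.5, wellSigma = 1.0, wellShift = 1.2,
    bbWellDepth = 0.15, bbScDepth = 0.10,
    epsHB = 1.2, rHB = 6.5, auxMax = 7.5, hbInner = 4.2,
    electro = list(lambdaD = 10, cutoff = 30, epsR = 80, ke = 332.06),
    nSteps = nSteps, nStepsElec = 10,
    bondCACA = c(3.72, 3.88), bondCA13 = c(4.40, 7.70),
    bondCASC = c(1.60, 2.40), scOffset = 2.0,
    disulfide = c(3.0, 6.0),
    ghostRate = 0.1, sampleInterval = 1000,
    helixRise = 1.5, helixTwist = 100, helixRadius = 2.3, caSpacing = 3.8)
}

# continuous sidechain-sidechain profile: hydrophobic gaussian well plus
# screened Coulomb for charged pairs
.scProfile <- function(ff, hc, hi, hj, qi, qj) {
  depth <- ff$eps0 + ff$epsH * hi * hj
  rm <- hc + ff$wellShift
  function(r) {
    u <- -depth * exp(-(r - rm)^2 / (2 * ff$wellSigma^2))
    if (qi != 0 && qj != 0)
      u <- u + screenedCoulomb(qi, qj, r, ff$electro)
    u
  }
}

.hNorm <- function(code) (.aaData[code, "kd"] + 4.5) / 9

# Build (with caching) the pair potential for two beads.  Returns an index
# into the growing potential list held in `env`.
.pairPotIndex <- function(env, key, builder) {
  idx <- env$index[[key]]
  if (!is.null(idx)) return(idx)
  pot <- builder()
  env$pots[[length(env$pots) + 1L]] <- pot
  env$index[[key]] <- length(env$pots)
  length(env$pots)
}

# Assign non-bonded potentials, bond potentials, exclusions and
# hydrogen-bond machinery for a particle table.  Returns the filled
# MolecularSystem given coordinates.
.buildSystem <- function(particles, coords, bonds, ff) {
  n <- nrow(particles)
  env <- new.env(parent = emptyenv())
  env$pots <- list()
  env$index <- list()

  pairPot <- matrix(0L, n, n)
  hbPot <- matrix(0L, n, n)
  hbAux <- matrix(0L, n, n)
  hbFormed <- matrix(FALSE, n, n)

  # bonds first (they override any non-bonded assignment)
  if (nrow(bonds)) {
    for (b in seq_len(nrow(bonds))) {
      key <- sprintf("bond:%.4f:%.4f", bonds$dmin[b], bonds$dmax[b])
      k <- .pairPotIndex(env, key, function()
        stepPotential(bonds$dmin[b], bonds$dmax[b], 0, bond = TRUE))
      pairPot[bonds$i[b], bonds$j[b]] <- k
      pairPot[bonds$j[b], bonds$i[b]] <- k
    }
  }
  bondedKey <- if (nrow(bonds))
    paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j)) else character(0)

  ch <- particles$chain; res <- particles$resIndex
  role <- particles$role; code <- particles$resCode
  rad <- particles$radius; q <- particles$charge

  # backbone index per (chain, residue) for the hydrogen-bond auxiliary bead
  bbOf <- new.env(parent = emptyenv())
  for (i in seq_len(n)) if (role[i] == "backbone")
    assign(paste(ch[i], res[i]), i, envir = bbOf)

  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (pairPot[i, j] != 0L) next                       # bonded
    if (ch[i] == ch[j] && abs(res[i] - res[j]) <= 1) next  # 1-2/1-3 excluded
    hc <- rad[i] + rad[j]
    bbPair <- role[i] == "backbone" && role[j] == "backbone"
    if (bbPair) {
      key <- sprintf("bb:%.3f", hc)
      pairPot[i, j] <- pairPot[j, i] <- .pairPotIndex(env, key, function()
        stepPotential(hc, ff$rHB, -ff$bbWellDepth))
      if (ch[i] != ch[j] || abs(res[i] - res[j]) >= 3) {
        hkey <- sprintf("hb:%.3f", hc)
        k <- .pairPotIndex(env, hkey, function()
          stepPotential(hc, c(ff$hbInner, ff$rHB), c(-0.5 * ff$epsHB, -ff$epsHB)))
        hbPot[i, j] <- hbPot[j, i] <- k
        a <- mget(paste(ch[i], res[i] + 1L), envir = bbOf,
                  ifnotfound = list(NULL))[[1]]
        if (is.null(a)) a <- mget(paste(ch[i], res[i] - 1L), envir = bbOf,
                                  ifnotfound = list(NULL))[[1]]
        if (!is.null(a)) { hbAux[i, j] <- a; hbAux[j, i] <- a }
      }
    } else if (role[i] == "sidechain" && role[j] == "sidechain") {
      ci <- code[i]; cj <- code[j]
      key <- paste("sc", paste(sort(c(ci, cj)), collapse = ""))
      charged <- q[i] != 0 && q[j] != 0
      pairPot[i, j] <- pairPot[j, i] <- .pairPotIndex(env, key, function() {
        f <- .scProfile(ff, hc, .hNorm(ci), .hNorm(cj), q[i], q[j])
        rmax <- if (charged) ff$electro$cutoff else ff$wellOut
        nst <- if (charged) ff$nStepsElec else ff$nSteps
        discretizePotential(f, hc, rmax, nst)
      })
    } else {
      key <- sprintf("bs:%.3f", hc)
      pairPot[i, j] <- pairPot[j, i] <- .pairPotIndex(env, key, function()
        stepPotential(hc, hc + 2.5, -ff$bbScDepth))
    }
  }

  new("MolecularSystem", particles = particles, coords = coords,
      bonds = bonds, potentials = env$pots, pairPot = pairPot,
      hbPot = hbPot, hbAux = hbAux, hbFormed = hbFormed, forceField = ff)
}
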