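# Small systems and oracles shared across tests.

# bare two-particle system with a single attractive well (no outer wall)
twoParticleWell <- function(sigma = 2, lambda = 4, eps = 1,
                            m = c(50, 50), r0 = 3) {
  particles <- data.frame(
    id = 1:2, chain = "T", resIndex = 1:2, resCode = "G",
    role = "backbone", mass = m, radius = sigma / 2, charge = 0,
    stringsAsFactors = FALSE)
  coords <- rbind(c(0, 0, 0), c(r0, 0, 0))
  colnames(coords) <- c("x", "y", "z")
  new("MolecularSystem", particles = particles, coords = coords,
      bonds = data.frame(i = integer(0), j = integer(0),
                         dmin = numeric(0), dmax = numeric(0)),
      potentials = list(stepPotential(sigma, lambda, -eps)),
      pairPot = matrix(c(0L, 1L, 1L, 0L), 2, 2),
      hbPot = matrix(0L, 2, 2), hbAux = matrix(0L, 2, 2),
      hbFormed = matrix(FALSE, 2, 2), forceField = defaultForceField())
}

# brute-force event-time oracle: scan the ballistic pair motion on a fine
# time grid and bisect the first shell-boundary crossing
bruteForceEventTime <- function(x1, v1, x2, v2, pot, tMax = 20,
                                nGrid = 200000) {
  boundaries <- c(pot@hardCore, pot@radii)
  tt <- seq(0, tMax, length.out = nGrid)
  r <- vapply(tt, function(t)
    sqrt(sum((x1 + v1 * t - x2 - v2 * t)^2)), numeric(1))
  region <- vapply(r, function(ri) sum(ri >= boundaries), numeric(1))
  ch <- which(diff(region) != 0)
  if (!length(ch)) return(Inf)
  lo <- tt[ch[1]]; hi <- tt[ch[1] + 1]
  target <- boundaries[max(region[ch[1]], region[ch[1] + 1])]
  f <- function(t) sqrt(sum((x1 + v1 * t - x2 - v2 * t)^2)) - target
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# exhaustive rigid-superposition RMSD by fine rotation-grid search
bruteForceRmsd <- function(X, Y, nAngle = 60) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  best <- Inf
  th <- seq(0, 2 * pi, length.out = nAngle + 1)[-(nAngle + 1)]
  ph <- seq(0, pi, length.out = nAngle / 2)
  for (a in th) for (b in ph) for (c in th) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3)
    R <- Rz1 %*% Ry %*% Rz2
    v <- sqrt(sum((Yc %*% R - Xc)^2) / nrow(X))
    if (v < best) best <- v
  }
  best
}

# helix residues 1..nHelix continued by an extended tail, as one chain
splitConformation <- function(seq, nHelix) {
  s <- as.character(seq)
  h <- buildChain(peptideSequence("h", substr(s, 1, nHelix)), "helix")
  e <- buildChain(peptideSequence("e", substr(s, nHelix + 1, nchar(s))),
                  "extended")
  full <- buildChain(seq, "helix")
  bbh <- which(h@particles$role == "backbone")
  co <- full@coords
  co[full@particles$resIndex <= nHelix, ] <- h@coords
  off <- h@coords[bbh[nHelix], ] + c(0, 0, 3.8) - e@coords[1, ]
  for (r in (nHelix + 1):nchar(s)) {
    sel <- which(full@particles$resIndex == r)
    sele <- which(e@particles$resIndex == r - nHelix)
    co[sel, ] <- sweep(e@coords[sele, , drop = FALSE], 2, -off)
  }
  list(system = full, coords = co)
}

# short two-chain peptide dimer used for engine/REX integration tests
smallDimer <- function(len = 8, separation = 15) {
  s <- substr(as.character(fixtureSequences()$hIAPP), 1, len)
  ch <- buildChain(peptideSequence("frag", s), "helix")
  assembleSystem(list(ch, ch), "proximal_parallel", separation = separation)
}
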