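# Building coarse-grained peptide systems from sequence.

#' Create a peptide sequence object
#'
#' @param id text label.
#' @param residues one-letter amino-acid string or character vector.
#' @param chain single-character chain id.
#' @export
peptideSequence <- function(id, residues, chain = "A") {
  if (length(residues) == 1 && nchar(residues) > 1)
    residues <- strsplit(residues, "")[[1]]
  obj <- new("PeptideSequence", id = id, residues = toupper(residues),
             chain = chain)
  obj
}

#' @export
setMethod("length", "PeptideSequence", function(x) length(x@residues))

#' @export
setMethod("as.character", "PeptideSequence",
          function(x) paste(x@residues, collapse = ""))

.particleRow <- function(id, chain, resIndex, resCode, role, ff) {
  if (role == "backbone") {
    data.frame(id = id, chain = chain, resIndex = resIndex,
               resCode = resCode, role = role, mass = ff$bbMass,
               radius = ff$bbRadius, charge = 0,
               stringsAsFactors = FALSE)
  } else {
    aa <- .aaData[resCode, ]
    data.frame(id = id, chain = chain, resIndex = resIndex,
               resCode = resCode, role = role,
               mass = max(aa$mass - ff$bbMass, 10),
               radius = aa$scRadius, charge = aa$charge,
               stringsAsFactors = FALSE)
  }
}

#' Build a one-chain coarse-grained system from sequence
#'
#' Places backbone beads either on an ideal alpha helix (rise 1.5 A and
#' 100 degree twist per residue, radius 2.3 A, so that the i,i+4 backbone
#' distance is ~6.2 A) or fully extended at 3.8 A Calpha-Calpha spacing on
#' a straight line.  Sidechain beads (absent for glycine) sit 2 A from
#' their backbone bead, pointing away from the helix axis or alternating
#' perpendicular to the extended line.  Consecutive backbone beads are
#' bonded at 3.8 A, next-nearest backbone beads carry a loose 1-3
#' constraint, and each sidechain is bonded to its backbone bead.
#'
#' @param seq a \linkS4class{PeptideSequence}.
#' @param startConformation "helix" or "extended".
#' @param ff force-field parameter list.
#' @return a \linkS4class{MolecularSystem} with one chain.
#' @export
buildChain <- function(seq, startConformation = c("helix", "extended"),
                       ff = defaultForceField()) {
  stopifnot(is(seq, "PeptideSequence"))
  validObject(seq)
  startConformation <- match.arg(startConformation)
  res <- seq@residues
  L <- length(res)

  if (startConformation == "helix") {
    # negative sense makes the helix right-handed (virtual CA torsion ~ +50)
    ang <- -(seq_len(L) - 1) * ff$helixTwist * pi / 180
    ca <- cbind(ff$helixRadius * cos(ang), ff$helixRadius * sin(ang),
                (seq_len(L) - 1) * ff$helixRise)
    scDir <- cbind(cos(ang), sin(ang), 0)      # radially outward
  } else {
    ca <- cbind((seq_len(L) - 1) * ff$caSpacing, 0, 0)
    side <- rep_len(c(1, -1), L)
    scDir <- cbind(0, side, 0)                 # alternating zigzag
  }

  rows <- list(); coords <- list(); id <- 0L
  bbId <- integer(L); scId <- rep(NA_integer_, L)
  for (i in seq_len(L)) {
    id <- id + 1L; bbId[i] <- id
    rows[[length(rows) + 1L]] <-
      .particleRow(id, seq@chain, i, res[i], "backbone", ff)
    coords[[length(coords) + 1L]] <- ca[i, ]
    if (res[i] != "G") {
      id <- id + 1L; scId[i] <- id
      rows[[length(rows) + 1L]] <-
        .particleRow(id, seq@chain, i, res[i], "sidechain", ff)
      coords[[length(coords) + 1L]] <- ca[i, ] + ff$scOffset * scDir[i, ]
    }
  }
  particles <- do.call(rbind, rows)
  coords <- do.call(rbind, coords)
  colnames(coords) <- c("x", "y", "z")

  bonds <- list()
  addBond <- function(i, j, rng)
    bonds[[length(bonds) + 1L]] <<- data.frame(i = i, j = j,
                                               dmin = rng[1], dmax = rng[2])
  if (L > 1) for (i in seq_len(L - 1)) addBond(bbId[i], bbId[i + 1], ff$bondCACA)
  if (L > 2) for (i in seq_len(L - 2)) addBond(bbId[i], bbId[i + 2], ff$bondCA13)
  for (i in seq_len(L)) if (!is.na(scId[i])) addBond(bbId[i], scId[i], ff$bondCASC)
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(i = integer(0), j = integer(0), dmin = numeric(0),
               dmax = numeric(0))

  sys <- .buildSystem(particles, coords, bonds, ff)
  validObject(sys)
  sys
}

.comOf <- function(sys) {
  m <- sys@particles$mass
  colSums(sys@coords * m) / sum(m)
}

# unit eigenvector of the coordinate covariance with smallest eigenvalue:
# the direction along which the chain is thinnest
.thinAxis <- function(coords) {
  cc <- sweep(coords, 2, colMeans(coords))
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  ev$vectors[, 3]
}

.randomRotation <- function() {
  # uniform rotation via random quaternion
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.interChainOverlap <- function(particles, coords) {
  ch <- particles$chain
  for (a in unique(ch)) for (b in unique(ch)) {
    if (a >= b) next
    ia <- which(ch == a); ib <- which(ch == b)
    d <- sqrt(outer(rowSums(coords[ia, , drop = FALSE]^2),
                    rowSums(coords[ib, , drop = FALSE]^2), "+") -
              2 * coords[ia, , drop = FALSE] %*% t(coords[ib, , drop = FALSE]))
    hc <- outer(particles$radius[ia], particles$radius[ib], "+")
    if (any(d < hc)) return(TRUE)
  }
  FALSE
}

#' Merge chains into one system
#'
#' \code{proximal_parallel} keeps every chain's internal conformation and
#' orientation and offsets successive chains along the direction in which
#' the first chain is thinnest, so that centres of mass are exactly
#' \code{separation} apart.  \code{random_orientation} applies a seeded
#' uniform random rotation to each added chain and places it in a random
#' direction at \code{separation}, retrying (up to 50 times) until no
#' inter-chain hard-core overlap remains.
#'
#' @param chains list of single-chain \linkS4class{MolecularSystem}s.
#' @param extraBonds optional data.frame (chainA, resA, roleA, chainB,
#'   resB, roleB, dmin, dmax) of cross-chain bonds, e.g. a disulfide.
#' @export
assembleSystem <- function(chains,
                           placement = c("proximal_parallel",
                                         "random_orientation"),
                           separation = 15, rngSeed = NULL,
                           extraBonds = NULL) {
  placement <- match.arg(placement)
  if (!length(chains)) stop("chains must be non-empty")
  if (length(chains) == 1 && is.null(extraBonds)) return(chains[[1]])
  if (!is.null(rngSeed)) set.seed(rngSeed)
  ff <- chains[[1]]@forceField

  # unique chain ids
  ids <- vapply(chains, function(s) unique(s@particles$chain), character(1))
  if (anyDuplicated(ids)) ids <- LETTERS[seq_along(chains)]

  base <- chains[[1]]
  com1 <- .comOf(base)
  axis <- .thinAxis(base@coords)
  placed <- list(base@coords)
  tables <- list(transform(base@particles, chain = ids[1]))

  for (k in seq_along(chains)[-1]) {
    sys <- chains[[k]]
    ok <- FALSE
    for (try in seq_len(50)) {
      cc <- sweep(sys@coords, 2, .comOf(sys))
      if (placement == "proximal_parallel") {
        target <- com1 + (k - 1) * separation * axis
      } else {
        cc <- cc %*% t(.randomRotation())
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        target <- com1 + separation * u
      }
      cand <- sweep(cc, 2, target, "+")
      particles <- do.call(rbind, c(tables,
        list(transform(sys@particles, chain = ids[k]))))
      coords <- do.call(rbind, c(placed, list(cand)))
      if (!.interChainOverlap(particles, coords)) { ok <- TRUE; break }
      if (placement == "proximal_parallel") break
    }
    if (!ok) stop("could not place chain ", k,
                  " without hard-core overlap (retries exhausted)")
    placed[[k]] <- cand
    tables[[k]] <- transform(sys@particles, chain = ids[k])
  }

  particles <- do.call(rbind, tables)
  particles$id <- seq_len(nrow(particles))
  rownames(particles) <- NULL
  coords <- do.call(rbind, placed)

  # re-index per-chain bonds into the merged numbering
  offset <- 0L; bonds <- list()
  for (k in seq_along(chains)) {
    b <- chains[[k]]@bonds
    if (nrow(b)) bonds[[k]] <- transform(b, i = i + offset, j = j + offset)
    offset <- offset + nrow(chains[[k]]@particles)
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(i = integer(0), j = integer(0), dmin = numeric(0),
               dmax = numeric(0))

  if (!is.null(extraBonds)) {
    for (b in seq_len(nrow(extraBonds))) {
      pi <- which(particles$chain == extraBonds$chainA[b] &
                  particles$resIndex == extraBonds$resA[b] &
                  particles$role == extraBonds$roleA[b])
      pj <- which(particles$chain == extraBonds$chainB[b] &
                  particles$resIndex == extraBonds$resB[b] &
                  particles$role == extraBonds$roleB[b])
      if (length(pi) != 1 || length(pj) != 1)
        stop("extra bond ", b, ": endpoints not found")
      bonds <- rbind(bonds, data.frame(i = pi, j = pj,
                                       dmin = extraBonds$dmin[b],
                                       dmax = extraBonds$dmax[b]))
    }
  }
  rownames(bonds) <- NULL

  sys <- .buildSystem(particles, coords, bonds, ff)
  validObject(sys)
  sys
}

#' Insulin monomer (A + B chain with an inter-chain disulfide)
#'
#' Builds the two insulin chains as ideal helices and links the Cys7
#' sidechain beads of the two chains by a bead-level disulfide bond
#' constraint.  Chain B is translated so that the linked sidechains start
#' 4.5 A apart, then rotated about the link point in a deterministic grid
#' search until no inter-chain hard-core overlap remains.
#'
#' @export
insulinMonomer <- function(ff = defaultForceField()) {
  fx <- fixtureSequences()
  A <- buildChain(fx$insulinA, "helix", ff)
  B <- buildChain(fx$insulinB, "helix", ff)

  sgA <- which(A@particles$resIndex == 7 & A@particles$role == "sidechain")
  sgB <- which(B@particles$resIndex == 7 & B@particles$role == "sidechain")

  ok <- FALSE
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  for (dir in dirs) {
    for (axis in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      for (angle in seq(0, 345, by = 15) * pi / 180) {
        K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                      -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
        Rm <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
        cc <- sweep(B@coords, 2, B@coords[sgB, ]) %*% t(Rm)
        cc <- sweep(cc, 2, A@coords[sgA, ] + 5 * dir, "+")
        particles <- rbind(A@particles, transform(B@particles, chain = "B"))
        coords <- rbind(A@coords, cc)
        if (!.interChainOverlap(particles, coords)) { ok <- TRUE; break }
      }
      if (ok) break
    }
    if (ok) break
  }
  if (!ok) stop("could not link insulin chains without overlap")

  nA <- nrow(A@particles)
  particles <- rbind(A@particles, transform(B@particles, chain = "B"))
  particles$id <- seq_len(nrow(particles))
  rownames(particles) <- NULL
  coords <- rbind(A@coords, cc)
  bonds <- rbind(A@bonds,
                 transform(B@bonds, i = i + nA, j = j + nA),
                 data.frame(i = sgA, j = sgB + nA,
                            dmin = ff$disulfide[1], dmax = ff$disulfide[2]))
  rownames(bonds) <- NULL
  sys <- .buildSystem(particles, coords, bonds, ff)
  validObject(sys)
  sys
}
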