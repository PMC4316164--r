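# Contact maps, RMSD, clustering protocol, secondary structure.

.frameCoords <- function(traj, f)
  matrix(traj@frames[f, , ], ncol = 3L)

.windowFrames <- function(traj, windowFraction) {
  # keep the last `windowFraction` of each run (by time within the run)
  keep <- logical(length(traj@times))
  for (r in unique(traj@runId)) {
    idx <- which(traj@runId == r)
    tt <- traj@times[idx]
    keep[idx] <- tt > min(tt) + (1 - windowFraction) * (max(tt) - min(tt))
  }
  which(keep)
}

#' Residue contact-frequency map
#'
#' Two residues are in contact in a frame when any bead pair between them
#' is within \code{cutoff} (default 5 A; at this coarse level "any atom
#' pair" maps to any bead pair).  Frequencies are the fraction of
#' retained frames in contact, computed over the last
#' \code{windowFraction} of each run (default the later half), pooling
#' runs with equal frame weight.  Per-residue any-partner binding
#' frequencies (frame-wise union over the partner chain) are computed at
#' the same time.
#'
#' @param traj a \linkS4class{Trajectory} (pool runs with
#'   \code{\link{poolTrajectories}} first).
#' @param chainPair character vector of two chain ids (may be equal for an
#'   intra-chain map).
#' @return a \linkS4class{ContactMap}.
#' @export
contactMap <- function(traj, chainPair, cutoff = 5, windowFraction = 0.5) {
  stopifnot(is(traj, "Trajectory"), length(chainPair) == 2)
  p <- traj@system@particles
  if (!all(chainPair %in% p$chain))
    stop("chain label(s) absent from trajectory: ",
         paste(setdiff(chainPair, p$chain), collapse = ", "))
  ia <- which(p$chain == chainPair[1])
  ib <- which(p$chain == chainPair[2])
  resA <- sort(unique(p$resIndex[ia])); resB <- sort(unique(p$resIndex[ib]))
  nA <- length(resA); nB <- length(resB)
  ra <- match(p$resIndex[ia], resA); rb <- match(p$resIndex[ib], resB)
  frames <- .windowFrames(traj, windowFraction)
  if (length(frames) < 2) stop("need at least 2 frames in the averaging window")

  freq <- matrix(0, nA, nB)
  bindA <- numeric(nA); bindB <- numeric(nB)
  same <- chainPair[1] == chainPair[2]
  for (f in frames) {
    X <- .frameCoords(traj, f)
    A <- X[ia, , drop = FALSE]; B <- X[ib, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    inc <- d2 < cutoff^2
    cr <- matrix(FALSE, nA, nB)
    hit <- which(inc, arr.ind = TRUE)
    if (nrow(hit)) cr[cbind(ra[hit[, 1]], rb[hit[, 2]])] <- TRUE
    if (same) diag(cr) <- FALSE
    freq <- freq + cr
    bindA <- bindA + (rowSums(cr) > 0)
    bindB <- bindB + (colSums(cr) > 0)
  }
  nf <- length(frames)
  new("ContactMap", freq = freq / nf, rowChain = chainPair[1],
      colChain = chainPair[2], cutoff = cutoff,
      windowFraction = windowFraction, nFrames = nf + 0,
      rowBinding = bindA / nf, colBinding = bindB / nf)
}

#' Per-residue partner-binding frequency
#'
#' Fraction of retained frames in which a residue contacts ANY residue of
#' the partner chain (frame-wise union recorded during map construction,
#' which dominates every single row entry).
#'
#' @param cm a two-chain \linkS4class{ContactMap}.
#' @param axis "row" or "col".
#' @export
residueBindingFrequency <- function(cm, axis = c("row", "col")) {
  stopifnot(is(cm, "ContactMap"))
  if (cm@rowChain == cm@colChain)
    stop("binding frequency needs a two-chain contact map")
  axis <- match.arg(axis)
  if (axis == "row") cm@rowBinding else cm@colBinding
}

#' Symmetrize a homodimer contact map
#'
#' A homodimer is exchange-symmetric, so the map is averaged with its
#' transpose: \code{out(i,j) = (in(i,j) + in(j,i)) / 2}.
#' @export
symmetrizeHomodimer <- function(cm) {
  stopifnot(is(cm, "ContactMap"))
  if (nrow(cm@freq) != ncol(cm@freq))
    stop("homodimer symmetrization needs equal chain lengths")
  cm@freq <- (cm@freq + t(cm@freq)) / 2
  b <- (cm@rowBinding + cm@colBinding) / 2
  cm@rowBinding <- b; cm@colBinding <- b
  cm
}

#' Minimal RMSD under rigid superposition (Kabsch)
#'
#' Optimal rotation and translation by SVD of the covariance matrix, with
#' the determinant correction that enforces a proper rotation.
#'
#' @param X,Y coordinate matrices (n x 3) of the same selection.
#' @param selection optional index vector applied to both.
#' @return RMSD in Angstrom.
#' @export
kabschRmsd <- function(X, Y, selection = NULL) {
  if (!is.null(selection)) {
    X <- X[selection, , drop = FALSE]
    Y <- Y[selection, , drop = FALSE]
  }
  if (nrow(X) != nrow(Y)) stop("selection length mismatch")
  if (nrow(X) < 3) stop("need at least 3 points")
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(Yc, Xc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(sum((Yc %*% R - Xc)^2) / nrow(X))
}

#' Low-energy frame selection by energy quantile
#'
#' Keeps the frames whose potential energy lies at or below the
#' \code{fraction} quantile of the pooled energies.  Ties at the cutoff
#' are included, so the selected fraction is at least \code{fraction}
#' (the minimal superset); the field convention for the clustering
#' protocol is about one-fourth of the frames.
#'
#' @param energies per-frame energies, kcal/mol.
#' @return integer frame indices in input order.
#' @export
selectLowEnergyFrames <- function(energies, fraction = 0.25) {
  if (!length(energies)) stop("empty input")
  if (length(energies) < 4) stop("need at least 4 frames")
  cutoff <- stats::quantile(energies, fraction, type = 1, names = FALSE)
  which(energies <= cutoff)
}

#' Sliding-window filtering of consecutive similar frames
#'
#' Greedy scan keeping a frame only when it is at least \code{W} time
#' units after the last kept frame of the same run (default 3500, the
#' midpoint of the conventional ~3000-4000 window).
#'
#' @param times frame times (sorted within each run).
#' @param W window in time units.
#' @param runId per-frame run index.
#' @return indices of kept frames.
#' @export
windowFilter <- function(times, W = 3500, runId = rep(1L, length(times))) {
  keep <- integer(0)
  for (r in unique(runId)) {
    idx <- which(runId == r)
    tt <- times[idx]
    if (is.unsorted(tt)) stop("frames must be time-sorted within a run")
    last <- -Inf
    for (k in seq_along(idx)) {
      if (tt[k] - last >= W) {
        keep <- c(keep, idx[k])
        last <- tt[k]
      }
    }
  }
  sort(keep)
}

#' Hierarchical clustering of conformations
#'
#' Agglomerative clustering (average linkage by default) on the pairwise
#' RMSD matrix, cut at \code{k} clusters (field convention: 50).  Clusters
#' are reported in descending size order with population fractions; each
#' cluster's centroid is the member with minimum summed RMSD to its
#' co-members.
#'
#' @param frames list of coordinate matrices, or a 3-d array
#'   (frames x beads x 3).
#' @param selection optional bead subset for the RMSD.
#' @return a \linkS4class{ClusterSet}.
#' @export
clusterStructures <- function(frames, k = 50, linkage = "average",
                              selection = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[1]), function(f)
      matrix(frames[f, , ], ncol = 3L))
  n <- length(frames)
  if (n < k) stop("fewer frames (", n, ") than clusters (", k, ")")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- kabschRmsd(frames[[i]], frames[[j]], selection)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  raw <- stats::cutree(hc, k = k)
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(k); relabel[as.integer(names(sizes))[ord]] <- seq_len(k)
  assignment <- relabel[raw]
  centroids <- vapply(seq_len(k), function(c) {
    members <- which(assignment == c)
    if (length(members) == 1) return(members)
    sums <- rowSums(D[members, members, drop = FALSE])
    members[which.min(sums)]
  }, integer(1))
  sizes <- as.integer(table(factor(assignment, levels = seq_len(k))))
  new("ClusterSet", assignment = as.integer(assignment),
      centroids = centroids, sizes = sizes,
      fractions = sizes / n, k = as.integer(k),
      frameIds = seq_len(n))
}

#' Full clustering protocol: energy selection, window filter, clustering
#'
#' The standard pipeline: pool runs, keep the lowest-energy quarter of
#' frames, drop consecutive similar structures with a sliding time
#' window, then cluster the survivors.
#'
#' @return list(clusters, frames, frameIndex) where frameIndex maps the
#'   clustered frames back into the pooled trajectory.
#' @export
clusterProtocol <- function(traj, k = 50, fraction = 0.25, W = 3500,
                            linkage = "average", selection = NULL) {
  stopifnot(is(traj, "Trajectory"))
  low <- selectLowEnergyFrames(traj@epot, fraction)
  kept <- low[windowFilter(traj@times[low], W, traj@runId[low])]
  frames <- lapply(kept, function(f) .frameCoords(traj, f))
  cl <- clusterStructures(frames, k = k, linkage = linkage,
                          selection = selection)
  list(clusters = cl, frames = frames, frameIndex = kept)
}

.virtualTorsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  # near-collinear backbone (fully extended) degenerates to the trans band
  ang <- function(u, v) acos(pmin(1, pmax(-1,
    sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  if (ang(-b1, b2) > 165 * pi / 180 || ang(-b2, b3) > 165 * pi / 180)
    return(180)
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Bead-level secondary-structure assignment
#'
#' Labels from backbone virtual dihedrals (the bead-level stand-in for
#' DSSP): a residue window is helical when 4 consecutive virtual torsions
#' lie within +-40 degrees of the ideal helical torsion (~50 deg), and
#' extended (strand) when 2 consecutive torsions lie in the trans band
#' (|tau| >= 140 deg); helix takes precedence, everything else is coil.
#' Chains shorter than 4 residues are all coil.
#'
#' @param coords N x 3 frame coordinates.
#' @param sys the matching \linkS4class{MolecularSystem}.
#' @return list(labels = per-residue factor in helix/strand/coil ordered
#'   by (chain, residue), content = named fractions).
#' @export
assignSecondaryStructure <- function(coords, sys) {
  p <- sys@particles
  labels <- character(0); nmres <- character(0)
  for (ch in unique(p$chain)) {
    bb <- which(p$chain == ch & p$role == "backbone")
    bb <- bb[order(p$resIndex[bb])]
    L <- length(bb)
    lab <- rep("coil", L)
    if (L >= 4) {
      tor <- vapply(2:(L - 2), function(i)
        .virtualTorsion(coords[bb[i - 1], ], coords[bb[i], ],
                        coords[bb[i + 1], ], coords[bb[i + 2], ]),
        numeric(1))
      helical <- tor >= 10 & tor <= 90
      strand <- abs(tor) >= 140
      nt <- length(tor)
      strandMark <- rep(FALSE, L)
      if (nt >= 2) for (w in seq_len(nt - 1)) if (all(strand[w:(w + 1)])) {
        i <- w + 1L                          # torsion index -> residue index
        strandMark[max(1, i - 1):min(L, i + 3)] <- TRUE
      }
      lab[strandMark] <- "strand"
      if (nt >= 4) for (w in seq_len(nt - 3)) if (all(helical[w:(w + 3)])) {
        i <- w + 1L
        lab[max(1, i - 1):min(L, i + 5)] <- "helix"
      }
    }
    labels <- c(labels, lab)
    nmres <- c(nmres, paste0(ch, ":", p$resIndex[bb]))
  }
  labels <- factor(labels, levels = c("helix", "strand", "coil"))
  names(labels) <- nmres
  content <- prop.table(table(labels))
  list(labels = labels,
       content = c(helix = unname(content["helix"]),
                   strand = unname(content["strand"]),
                   coil = unname(content["coil"])))
}

#' Helix content of every frame in a trajectory
#' @export
helixContent <- function(traj) {
  vapply(seq_len(nFrames(traj)), function(f)
    assignSecondaryStructure(.frameCoords(traj, f),
                             traj@system)$content[["helix"]],
    numeric(1))
}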