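test_that("contact frequencies follow the planted schedule", {
  tr <- plantedTrajectory(100, contactPlan = data.frame(i = 2, j = 4,
                                                        freq = 1))
  cm <- contactMap(tr, c("A", "B"))
  expect_equal(frequencyMatrix(cm)[2, 4], 1)

  tr0 <- plantedTrajectory(100, contactPlan = data.frame(i = 2, j = 4,
                                                         freq = 0))
  expect_equal(frequencyMatrix(contactMap(tr0, c("A", "B")))[2, 4], 0)

  # alternating 4 A / 8 A, even frame count in the window
  trh <- plantedTrajectory(200, contactPlan = data.frame(i = 3, j = 7,
                                                         freq = 0.5))
  cmh <- contactMap(trh, c("A", "B"))
  expect_equal(frequencyMatrix(cmh)[3, 7], 0.5)
  expect_true(all(frequencyMatrix(cmh) >= 0 & frequencyMatrix(cmh) <= 1))

  expect_error(contactMap(tr, c("A", "Z")), "absent")
})

test_that("contact maps are invariant under rigid-body motion of frames", {
  tr <- plantedTrajectory(60, contactPlan = data.frame(i = 2, j = 5,
                                                       freq = 0.5))
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr2 <- tr
  for (f in seq_len(nFrames(tr)))
    tr2@frames[f, , ] <- sweep(tr@frames[f, , ] %*% R, 2, c(7, -3, 11), "+")
  expect_equal(frequencyMatrix(contactMap(tr2, c("A", "B"))),
               frequencyMatrix(contactMap(tr, c("A", "B"))))
})

test_that("binding frequency is the frame-wise union over partners", {
  # residue 5 contacts partner residue 1 in odd frames, residue 2 in even
  tr <- plantedTrajectory(100, L = 6)
  ia <- 5
  for (k in seq_len(100)) {
    j <- if (k %% 2 == 1) 1 else 2
    tr@frames[k, nrow(tr@system@particles) / 2 + j, ] <-
      tr@frames[k, ia, ] + c(0, 0, 4)
  }
  cm <- contactMap(tr, c("A", "B"))
  bf <- residueBindingFrequency(cm, "row")
  expect_equal(bf[ia], 1)                       # union over partners
  expect_equal(max(frequencyMatrix(cm)[ia, ]), 0.5)
  # union dominates any single pair entry
  expect_true(all(bf >= apply(frequencyMatrix(cm), 1, max) - 1e-12))
  expect_error(residueBindingFrequency(
    contactMap(tr, c("A", "A")), "row"))
})

test_that("homodimer maps symmetrize by transpose averaging", {
  tr <- plantedTrajectory(50, contactPlan = data.frame(i = 2, j = 6,
                                                       freq = 1))
  cm <- contactMap(tr, c("A", "B"))
  sym <- symmetrizeHomodimer(cm)
  m <- frequencyMatrix(cm)
  expect_equal(frequencyMatrix(sym), (m + t(m)) / 2)
  expect_equal(frequencyMatrix(sym)[2, 6], 0.5)
  expect_equal(frequencyMatrix(sym)[6, 2], 0.5)
  # already-symmetric input is unchanged
  expect_equal(frequencyMatrix(symmetrizeHomodimer(sym)),
               frequencyMatrix(sym))
})

test_that("Kabsch RMSD is exact for congruent sets and matches brute force", {
  X <- matrix(rnorm(30, sd = 4), 10, 3)
  expect_equal(kabschRmsd(X, X), 0, tolerance = 1e-10)
  th <- 0.83
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  Y <- sweep(X %*% R, 2, c(3, -2, 9), "+")
  expect_lt(kabschRmsd(X, Y), 1e-8)
  expect_equal(kabschRmsd(X, Y), kabschRmsd(Y, X), tolerance = 1e-10)

  set.seed(301)
  A <- matrix(rnorm(12, sd = 3), 4, 3)
  B <- matrix(rnorm(12, sd = 3), 4, 3)
  expect_equal(kabschRmsd(A, B), bruteForceRmsd(A, B, nAngle = 72),
               tolerance = 1e-3)
  # independent library cross-check
  fit <- suppressWarnings(bio3d::fit.xyz(as.vector(t(A)), as.vector(t(B))))
  ref <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - A)^2)))
  expect_equal(kabschRmsd(A, B), ref, tolerance = 1e-6)

  expect_error(kabschRmsd(A, B[1:3, ]))
  expect_error(kabschRmsd(A[1:2, ], B[1:2, ]))
})

test_that("low-energy selection keeps the quantile with its ties", {
  set.seed(303)
  e <- sample(seq_len(10000))          # all distinct
  sel <- selectLowEnergyFrames(e, 0.25)
  expect_equal(length(sel), 2500)
  expect_true(all(e[sel] <= 2500))

  expect_equal(selectLowEnergyFrames(rep(1, 8), 0.25), 1:8)  # tie rule
  expect_equal(selectLowEnergyFrames(e, 1), seq_along(e))
  expect_error(selectLowEnergyFrames(numeric(0)))
})

test_that("the sliding-window filter keeps frames W apart per run", {
  tt <- seq(0, 20000, by = 1000)
  kept <- windowFilter(tt, W = 3500)
  expect_equal(tt[kept], seq(0, 20000, by = 4000))  # every 4th frame
  expect_equal(windowFilter(5), 1L)
  expect_equal(windowFilter(tt, W = 0), seq_along(tt))
  # runs are filtered independently
  kept2 <- windowFilter(c(tt, tt), W = 3500,
                        runId = rep(1:2, each = length(tt)))
  expect_equal(length(kept2), 2 * length(kept))
  expect_error(windowFilter(c(3, 1, 2), W = 1))
})

test_that("clustering recovers planted partitions and honest centroids", {
  tr <- plantedTrajectory(60, clusterPlan = c(10, 20, 30), seed = 305)
  pA <- which(tr@system@particles$chain == "A")
  frames <- lapply(seq_len(60), function(f)
    matrix(tr@frames[f, pA, ], ncol = 3))
  cl <- clusterStructures(frames, k = 3)
  expect_equal(clusterSizes(cl), c(30L, 20L, 10L))
  # planted blocks map to single clusters
  expect_equal(length(unique(cl@assignment[1:10])), 1)
  expect_equal(length(unique(cl@assignment[11:30])), 1)
  expect_equal(length(unique(cl@assignment[31:60])), 1)
  expect_equal(sum(cl@fractions), 1)

  # centroid property verified by exhaustive within-cluster RMSD sums
  D <- matrix(0, 60, 60)
  for (i in 1:59) for (j in (i + 1):60)
    D[i, j] <- D[j, i] <- kabschRmsd(frames[[i]], frames[[j]])
  for (c in seq_len(3)) {
    members <- which(cl@assignment == c)
    sums <- rowSums(D[members, members, drop = FALSE])
    expect_equal(clusterCentroids(cl)[c], members[which.min(sums)])
  }

  # n == k: singletons, each its own centroid
  cl1 <- clusterStructures(frames[1:5], k = 5)
  expect_equal(clusterSizes(cl1), rep(1L, 5))
  expect_setequal(clusterCentroids(cl1), 1:5)
  expect_error(clusterStructures(frames[1:3], k = 5))
})

test_that("the clustering pipeline is deterministic for fixed input", {
  tr <- plantedTrajectory(80, clusterPlan = c(40, 40), seed = 307)
  tr@epot <- rep(c(0, 1), 40)   # energies tag alternate frames
  a <- clusterProtocol(tr, k = 2, fraction = 0.5, W = 0)
  b <- clusterProtocol(tr, k = 2, fraction = 0.5, W = 0)
  expect_identical(a$clusters@assignment, b$clusters@assignment)
  expect_identical(a$frameIndex, b$frameIndex)
})

test_that("secondary structure labels ideal, extended and split chains", {
  fx <- fixtureSequences()
  hx <- buildChain(fx$hIAPP, "helix")
  ss <- assignSecondaryStructure(coordinates(hx), hx)
  expect_gte(ss$content[["helix"]], 0.8)

  ex <- buildChain(fx$hIAPP, "extended")
  se <- assignSecondaryStructure(coordinates(ex), ex)
  expect_equal(se$content[["helix"]], 0)

  sp <- splitConformation(fx$hIAPP, 19)
  sl <- assignSecondaryStructure(sp$coords, sp$system)
  expect_lte(abs(sum(sl$labels == "helix") - 19), 1)   # planted split +-1
  expect_lte(abs(sum(sl$labels == "strand") - 18), 1)

  short <- buildChain(peptideSequence("s", "ACD"), "helix")
  s3 <- assignSecondaryStructure(coordinates(short), short)
  expect_equal(s3$content[["coil"]], 1)
})
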