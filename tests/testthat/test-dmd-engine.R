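test_that("pair event prediction solves the ballistic quadratic", {
  pot <- stepPotential(1, 1.5, 0)   # summed hard core 1 A, tiny dead shell
  # head-on: gap of 2 A closed at 2 A per time unit
  ev <- nextPairEvent(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0), c(-1, 0, 0),
                      stepPotential(1, 1.2, 0))
  # first crossing is the outer shell radius, then the core
  expect_lt(ev$time, 1)
  evCore <- nextPairEvent(c(0, 0, 0), c(1, 0, 0), c(1.1, 0, 0),
                          c(-1, 0, 0), pot)
  expect_equal(evCore$kind, "core_reflection")
  expect_equal(evCore$time, (1.1 - 1) / 2, tolerance = 1e-12)

  # receding pair outside every shell: no event
  none <- nextPairEvent(c(0, 0, 0), c(-1, 0, 0), c(3, 0, 0), c(1, 0, 0),
                        stepPotential(1, 2, -1))
  expect_identical(none$time, Inf)
  expect_equal(none$kind, "none")
})

test_that("oblique event times match a brute-force trajectory scan", {
  pot <- stepPotential(1.5, 4.5, -0.8)
  set.seed(21)
  for (k in 1:6) {
    x1 <- runif(3, -1, 1); x2 <- x1 + c(6, 1.5, -1) + runif(3, -0.3, 0.3)
    v1 <- runif(3, -0.5, 0.5); v2 <- runif(3, -0.5, 0.5)
    v1[1] <- 0.8  # ensure approach
    ev <- nextPairEvent(x1, v1, x2, v2, pot)
    ref <- bruteForceEventTime(x1, v1, x2, v2, pot)
    if (is.finite(ref)) expect_equal(ev$time, ref, tolerance = 1e-6)
  }
})

test_that("event resolution conserves momentum and energy exactly", {
  # equal masses, head-on core reflection: velocities exchanged
  r <- resolvePairEvent(c(0, 0, 0), c(1, 0, 0), 5,
                        c(2, 0, 0), c(-1, 0, 0), 5, wall = TRUE)
  expect_equal(r$v1, c(-1, 0, 0))
  expect_equal(r$v2, c(1, 0, 0))

  # well entry of depth 1 kcal/mol: radial KE gains exactly the depth
  m1 <- 3; m2 <- 7; mu <- 1 / (1 / m1 + 1 / m2)
  v1 <- c(0.4, 0.1, 0); v2 <- c(-0.3, 0, 0.2)
  r2 <- resolvePairEvent(c(0, 0, 0), v1, m1, c(5, 0, 0), v2, m2, dU = -1)
  vr <- (v1 - v2)[1]; vrNew <- (r2$v1 - r2$v2)[1]
  expect_true(r2$crossed)
  expect_equal(0.5 * mu * vrNew^2, 0.5 * mu * vr^2 + 1, tolerance = 1e-12)
  # energy: delta KE == -dU
  keBefore <- 0.5 * m1 * sum(v1^2) + 0.5 * m2 * sum(v2^2)
  keAfter <- 0.5 * m1 * sum(r2$v1^2) + 0.5 * m2 * sum(r2$v2^2)
  expect_equal(keAfter - keBefore, 1, tolerance = 1e-12)
  # momentum: change below 1e-12
  expect_lt(max(abs(m1 * r2$v1 + m2 * r2$v2 - (m1 * v1 + m2 * v2))), 1e-12)

  # exit attempt with insufficient radial KE: bounce, energy unchanged
  r3 <- resolvePairEvent(c(0, 0, 0), c(0.01, 0, 0), m1,
                         c(5, 0, 0), c(-0.01, 0, 0), m2, dU = 10)
  expect_false(r3$crossed)
  keB <- 0.5 * m1 * sum(r3$v1^2) + 0.5 * m2 * sum(r3$v2^2)
  expect_equal(keB, 0.5 * m1 * 1e-4 + 0.5 * m2 * 1e-4, tolerance = 1e-14)
})

test_that("thermostat kicks sample the Maxwell-Boltzmann distribution", {
  expect_equal(thermostatKick(5, 0), matrix(0, 1, 3))
  expect_error(thermostatKick(5, -1))
  set.seed(31)
  v <- thermostatKick(rep(2.5, 1e5), 0.6)
  ke <- 0.5 * 2.5 * rowSums(v^2)
  expect_equal(mean(ke), 1.5 * 0.6, tolerance = 0.02)
  set.seed(99); a <- thermostatKick(rep(1, 10), 1)
  set.seed(99); b <- thermostatKick(rep(1, 10), 1)
  expect_identical(a, b)
})

test_that("velocities under the thermostat pass a KS normality check", {
  toy <- makeToySystem("harmonic_like_chain", nBeads = 4)
  set.seed(41)
  tr <- runDMD(toy$system, 2e4, 0.65, sampleInterval = 20)
  # skip equilibration; frames are ~2 ghost-collision times apart
  v <- as.vector(tr@velFrames[-(1:20), , ])
  expect_gt(length(v), 1e4)
  ks <- suppressWarnings(
    stats::ks.test(v, "pnorm", 0, sqrt(0.65 / 50)))
  expect_gt(ks$p.value, 0.01)
})

test_that("a bound pair oscillates with the closed-form chord period", {
  sys <- twoParticleWell(sigma = 2, lambda = 4, eps = 1, r0 = 3)
  vrel <- 0.1   # radial KE = 0.125 < eps: stays bound
  vel <- rbind(c(vrel / 2, 0, 0), c(-vrel / 2, 0, 0))
  period <- 2 * (4 - 2) / vrel
  tr <- runDMD(sys, 2 * period, 0, thermostat = FALSE, velocities = vel,
               sampleInterval = 2 * period)
  d <- sqrt(sum((tr@finalCoords[1, ] - tr@finalCoords[2, ])^2))
  expect_equal(d, 3, tolerance = 1e-9)
  expect_equal(tr@finalVelocities, vel, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("duration zero returns a single frame equal to the input state", {
  sys <- twoParticleWell()
  tr <- runDMD(sys, 0, 0.5, seed = 1)
  expect_equal(nFrames(tr), 1)
  expect_equal(coordinates(tr, 1), coordinates(sys), ignore_attr = TRUE)
})

test_that("event dynamics conserve energy and momentum without thermostat", {
  sys <- smallDimer(6, separation = 12)
  set.seed(51)
  vel <- thermostatKick(particleTable(sys)$mass, 0.6)
  tr <- runDMD(sys, 600, 0.6, thermostat = FALSE, velocities = vel,
               sampleInterval = 20)
  expect_gt(tr@nEvents, 1e4)
  E <- tr@epot + tr@ekin
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-6)
  # total momentum constant
  m <- particleTable(sys)$mass
  p0 <- colSums(vel * m)
  p1 <- colSums(tr@finalVelocities * m)
  expect_lt(max(abs(p1 - p0)), 1e-9)
})

test_that("tracked potential energy matches recomputation from coordinates", {
  sys <- smallDimer(5)
  set.seed(61)
  tr <- runDMD(sys, 300, 0.6, sampleInterval = 300)
  sysF <- tr@system; sysF@coords <- tr@finalCoords
  expect_equal(tr@epot[nFrames(tr)], totalEnergy(sysF)$potential,
               tolerance = 1e-9)
})

test_that("planted three-particle configuration gives the hand-summed energy", {
  sys <- twoParticleWell()          # base pieces reused
  particles <- rbind(sys@particles,
                     transform(sys@particles[1, ], id = 3, resIndex = 3))
  coords <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3.5, 0))
  colnames(coords) <- c("x", "y", "z")
  pp <- matrix(1L, 3, 3); diag(pp) <- 0L
  sys3 <- new("MolecularSystem", particles = particles, coords = coords,
              bonds = sys@bonds, potentials = sys@potentials,
              pairPot = pp, hbPot = matrix(0L, 3, 3),
              hbAux = matrix(0L, 3, 3), hbFormed = matrix(FALSE, 3, 3),
              forceField = sys@forceField)
  # pairs 1-2 (3 A) and 1-3 (3.5 A) inside the well; 2-3 (4.6 A) outside
  expect_equal(totalEnergy(sys3)$potential, -2)
  expect_equal(totalEnergy(sys3)$kinetic, 0)
})

test_that("identical seed and configuration reproduce the trajectory bytes", {
  sys <- smallDimer(5)
  t1 <- runDMD(sys, 150, 0.6, seed = 77)
  t2 <- runDMD(sys, 150, 0.6, seed = 77)
  expect_identical(t1@frames, t2@frames)
  expect_identical(t1@epot, t2@epot)
})

test_that("no sampled frame violates the hard-core exclusion", {
  sys <- smallDimer(6)
  set.seed(81)
  tr <- runDMD(sys, 400, 0.65, sampleInterval = 10)
  p <- particleTable(sys)
  for (f in seq(1, nFrames(tr), by = 8)) {
    co <- coordinates(tr, f)
    d <- as.matrix(dist(co))
    for (i in seq_len(nrow(p) - 1)) for (j in (i + 1):nrow(p)) {
      k <- sys@pairPot[i, j]
      if (k == 0) next
      expect_gte(d[i, j], sys@potentials[[k]]@hardCore - 1e-9)
    }
  }
})

test_that("hydrogen bonding follows the sequence-separation rule and books energy", {
  sys <- smallDimer(8)
  p <- particleTable(sys)
  bbA <- which(p$chain == "A" & p$role == "backbone")
  # same chain, neighbours: never hydrogen-bond capable
  expect_equal(sys@hbPot[bbA[1], bbA[2]], 0L)
  expect_equal(sys@hbPot[bbA[1], bbA[3]], 0L)
  expect_gt(sys@hbPot[bbA[1], bbA[4]], 0L)   # i, i+3 allowed
  bbB <- which(p$chain == "B" & p$role == "backbone")
  expect_gt(sys@hbPot[bbA[1], bbB[1]], 0L)   # inter-chain always allowed

  set.seed(91)
  tr <- runDMD(sys, 400, 0.55, sampleInterval = 400)
  # energy bookkeeping with reactions still matches recomputation
  sysF <- tr@system; sysF@coords <- tr@finalCoords
  expect_equal(tr@epot[nFrames(tr)], totalEnergy(sysF)$potential,
               tolerance = 1e-9)
  expect_true(any(sysF@hbFormed))   # helix start: bonds do form
})
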