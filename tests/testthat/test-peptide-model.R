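test_that("buildChain produces the expected chain topology", {
  fx <- fixtureSequences()
  sys <- buildChain(fx$hIAPP, "helix")
  p <- particleTable(sys)
  expect_equal(length(unique(p$resIndex)), 37)
  caca <- sys@bonds[abs(sys@bonds$dmin - 3.72) < 1e-9, ]
  expect_equal(nrow(caca), 36)  # consecutive backbone bonds

  one <- buildChain(peptideSequence("x", "G"), "extended")
  expect_equal(nrow(one@bonds), 0)
  expect_gte(nParticles(one), 1)
})

test_that("ideal helix geometry places i,i+4 backbone beads ~6.2 A apart", {
  sys <- buildChain(fixtureSequences()$hIAPP, "helix")
  bb <- which(particleTable(sys)$role == "backbone")
  # oracle: evaluate the parametric helix coordinates directly
  r <- 2.3; rise <- 1.5; tw <- 100 * pi / 180
  expectd <- sqrt((2 * r * sin(2 * tw))^2 + (4 * rise)^2)
  d <- sqrt(sum((coordinates(sys)[bb[1], ] - coordinates(sys)[bb[5], ])^2))
  expect_equal(d, expectd, tolerance = 1e-9)
  expect_equal(d, 6.2, tolerance = 0.01)
})

test_that("unknown residue codes are rejected with the offending position", {
  expect_error(peptideSequence("bad", "ACDXG"), "position 4")
})

test_that("discretizePotential averages the continuous energy per shell", {
  # constant function: every step equals the constant
  p <- discretizePotential(function(r) 2.5, 1, 3, 7)
  expect_equal(p@energies, rep(2.5, 7))
  expect_equal(stepEnergy(p, 3.5), 0)   # zero beyond rMax

  # single step: shell average
  f <- function(r) r^2
  p1 <- discretizePotential(f, 1, 3, 1)
  expect_equal(p1@energies, integrate(f, 1, 3)$value / 2, tolerance = 1e-8)

  # screened Coulomb on [2, 30], 8 steps, against per-shell quadrature
  ff <- defaultForceField()
  sc <- function(r) screenedCoulomb(1, 1, r, ff$electro)
  p8 <- discretizePotential(sc, 2, 30, 8)
  b <- seq(2, 30, length.out = 9)
  oracle <- vapply(1:8, function(k)
    integrate(sc, b[k], b[k + 1])$value / (b[k + 1] - b[k]), numeric(1))
  expect_equal(p8@energies, oracle, tolerance = 1e-6)
  expect_error(discretizePotential(sc, 2, 30, 0))
  expect_error(discretizePotential(sc, 2, 1, 4))
})

test_that("discretization converges to the continuous Boltzmann average", {
  # two-particle radial Boltzmann average of the energy, measure r^2 dr
  ff <- defaultForceField()
  f <- function(r) -1.2 * exp(-(r - 4)^2 / 2)
  Tv <- 0.6; hc <- 2.8; rmax <- 9
  num <- integrate(function(r) r^2 * f(r) * exp(-f(r) / Tv), hc, rmax)$value
  den <- integrate(function(r) r^2 * exp(-f(r) / Tv), hc, rmax)$value
  contRef <- num / den
  stepAvg <- function(n) {
    p <- discretizePotential(f, hc, rmax, n)
    u <- function(r) stepEnergy(p, r)
    nn <- integrate(function(r) r^2 * vapply(r, u, 1) *
                      exp(-vapply(r, u, 1) / Tv), hc, rmax,
                    subdivisions = 2000, stop.on.error = FALSE)$value
    dd <- integrate(function(r) r^2 * exp(-vapply(r, u, 1) / Tv), hc, rmax,
                    subdivisions = 2000, stop.on.error = FALSE)$value
    nn / dd
  }
  expect_gt(abs(stepAvg(2) - contRef) / abs(contRef),
            abs(stepAvg(64) - contRef) / abs(contRef))
  expect_lt(abs(stepAvg(64) - contRef) / abs(contRef), 0.01)
})

test_that("every constructed potential is exactly zero beyond its range", {
  sys <- buildChain(fixtureSequences()$hIAPP, "helix")
  for (p in sys@potentials) {
    if (p@bond) next
    expect_identical(stepEnergy(p, max(p@radii) * 1.0001), 0)
  }
})

test_that("screened Coulomb has the closed-form profile and hard cutoff", {
  ff <- defaultForceField()$electro
  expect_equal(screenedCoulomb(0, 1, 5), 0)
  expect_equal(screenedCoulomb(1, -1, 30), 0)       # at the 30 A cutoff
  expect_equal(screenedCoulomb(1, 1, 31), 0)
  # ratio U(r)/U(r + lambdaD) = e (r + lambdaD) / r below the cutoff
  r <- 7
  rat <- screenedCoulomb(1, 1, r) / screenedCoulomb(1, 1, r + ff$lambdaD)
  expect_equal(rat, exp(1) * (r + ff$lambdaD) / r, tolerance = 1e-12)
  expect_error(screenedCoulomb(1, 1, 0))
})

test_that("assembleSystem placement contracts hold", {
  ch <- buildChain(peptideSequence("frag", "KCNTATCA"), "extended")
  expect_identical(assembleSystem(list(ch)), ch)

  dim2 <- assembleSystem(list(ch, ch), "proximal_parallel", separation = 10)
  p <- particleTable(dim2); m <- p$mass
  comA <- colSums(coordinates(dim2)[p$chain == "A", ] * m[p$chain == "A"]) /
    sum(m[p$chain == "A"])
  comB <- colSums(coordinates(dim2)[p$chain == "B", ] * m[p$chain == "B"]) /
    sum(m[p$chain == "B"])
  expect_equal(sqrt(sum((comA - comB)^2)), 10, tolerance = 1e-6)

  r1 <- assembleSystem(list(ch, ch), "random_orientation",
                       separation = 25, rngSeed = 42)
  r2 <- assembleSystem(list(ch, ch), "random_orientation",
                       separation = 25, rngSeed = 42)
  expect_identical(coordinates(r1), coordinates(r2))

  # no configuration may start below the summed hard cores
  for (seed in 1:5) {
    sys <- assembleSystem(list(ch, ch), "random_orientation",
                          separation = 25, rngSeed = seed)
    co <- coordinates(sys); rad <- particleTable(sys)$radius
    chv <- particleTable(sys)$chain
    ia <- which(chv == "A"); ib <- which(chv == "B")
    d <- sqrt(outer(rowSums(co[ia, ]^2), rowSums(co[ib, ]^2), "+") -
              2 * co[ia, ] %*% t(co[ib, ]))
    expect_true(all(d >= outer(rad[ia], rad[ib], "+")))
  }
})

test_that("insulin monomer carries the inter-chain disulfide constraint", {
  ins <- insulinMonomer()
  p <- particleTable(ins)
  expect_setequal(unique(p$chain), c("A", "B"))
  expect_equal(sum(p$chain == "A" & p$role == "backbone"), 21)
  expect_equal(sum(p$chain == "B" & p$role == "backbone"), 30)
  ss <- ins@bonds[ins@bonds$dmax == defaultForceField()$disulfide[2], ]
  expect_equal(nrow(ss), 1)
  d <- sqrt(sum((coordinates(ins)[ss$i, ] - coordinates(ins)[ss$j, ])^2))
  expect_gte(d, ss$dmin); expect_lte(d, ss$dmax)
})
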