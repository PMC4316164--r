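# two-level closed forms used as oracles throughout
schottkyCv <- function(T, dE, g0 = 1, g1 = 1) {
  p1 <- g1 * exp(-dE / T) / (g0 + g1 * exp(-dE / T))
  (dE / T)^2 * p1 * (1 - p1)
}
schottkyE <- function(T, dE, g0 = 1, g1 = 1) {
  dE * g1 * exp(-dE / T) / (g0 + g1 * exp(-dE / T))
}

test_that("single-temperature WHAM reweights the histogram directly", {
  set.seed(201)
  s <- list(sampleTwoLevel(5000, 0.6, dE = 1))
  h <- energyHistogramSet(s, 0.6, binWidth = 0.5)
  w <- solveWham(h)
  expect_equal(w@f, 0)
  lo <- w@logOmega[is.finite(w@logOmega)]
  # Omega proportional to H exp(+E/T)
  keep <- rowSums(h@counts) > 0
  ref <- log(h@counts[keep, 1]) + h@binMid[keep] / 0.6
  expect_equal(diff(lo), diff(ref), tolerance = 1e-9)
})

test_that("merging identical sample sets leaves the solution unchanged", {
  set.seed(203)
  a <- sampleTwoLevel(4000, 0.6, dE = 1)
  w1 <- solveWham(energyHistogramSet(list(a), 0.6, binWidth = 0.5))
  w2 <- solveWham(energyHistogramSet(list(a, a), c(0.6, 0.6),
                                     binWidth = 0.5))
  n1 <- w1@logOmega - max(w1@logOmega)
  n2 <- w2@logOmega - max(w2@logOmega)
  expect_equal(n1, n2, tolerance = 1e-6)
})

test_that("WHAM recovers a known two-level density of states", {
  toy <- makeToySystem("two_level", dE = 1.9, g0 = 1, g1 = 8)
  temps <- seq(0.5, 0.675, length.out = 8)
  set.seed(205)
  samples <- lapply(temps, function(T) toy$reference$sampler(20000, T))
  w <- solveWham(energyHistogramSet(samples, temps))
  expect_true(w@converged)
  expect_lte(w@residual, w@tol)
  lo <- w@logOmega[is.finite(w@logOmega)]
  expect_equal(length(lo), 2)
  expect_equal(exp(diff(lo)), 8, tolerance = 0.05)   # Omega ratio g1/g0
})

test_that("non-overlapping histograms are diagnosed with the gap", {
  expect_error(
    solveWham(energyHistogramSet(list(c(0, 0.1, 0.2), c(40, 40.1)),
                                 c(0.5, 0.6), binWidth = 1)),
    "no overlap")
})

test_that("specific heat matches the Schottky closed form within 1%", {
  toy <- makeToySystem("two_level", dE = 1.9, g0 = 1, g1 = 8)
  temps <- seq(0.5, 0.675, length.out = 8)
  set.seed(207)
  samples <- lapply(temps, function(T) toy$reference$sampler(20000, T))
  w <- solveWham(energyHistogramSet(samples, temps))
  grid <- seq(0.45, 0.75, by = 0.01)
  tab <- thermoTable(specificHeat(w, grid))
  ref <- schottkyCv(grid, 1.9, 1, 8)
  expect_lt(max(abs(tab$Cv - ref) / ref), 0.01)
  expect_true(all(tab$Cv >= 0))

  # peak temperature recovered within one grid step of the analytic peak
  expect_lt(abs(grid[which.max(tab$Cv)] - grid[which.max(ref)]),
            0.01 + 1e-12)

  # Cv integral check: <E>(T2) - <E>(T1) = integral of Cv dT
  fine <- seq(0.5, 0.675, by = 0.0005)
  tf <- thermoTable(specificHeat(w, fine))
  lhs <- tf$Emean[length(fine)] - tf$Emean[1]
  rhs <- sum((tf$Cv[-1] + tf$Cv[-length(fine)]) / 2 * diff(fine))
  expect_equal(lhs, rhs, tolerance = 1e-4)
})

test_that("a single occupied energy level has zero specific heat", {
  w <- solveWham(energyHistogramSet(list(rep(1.0, 100)), 0.6,
                                    binWidth = 0.5))
  tab <- thermoTable(specificHeat(w, seq(0.4, 0.8, by = 0.05)))
  expect_equal(tab$Cv, rep(0, nrow(tab)), tolerance = 1e-12)
})

test_that("observable reweighting is exact for constants and self-consistent for E", {
  toy <- makeToySystem("two_level", dE = 1.5, g0 = 1, g1 = 1)
  temps <- seq(0.5, 0.675, length.out = 8)
  set.seed(209)
  E <- lapply(temps, function(T) toy$reference$sampler(15000, T))
  w <- solveWham(energyHistogramSet(E, temps))
  grid <- seq(0.5, 0.675, by = 0.025)

  const <- reweightObservable(lapply(E, function(e)
    data.frame(E = e, O = 3.25)), w, grid)
  expect_equal(const$O, rep(3.25, length(grid)), tolerance = 1e-12)

  selfE <- reweightObservable(lapply(E, function(e)
    data.frame(E = e, O = e)), w, grid)
  tab <- thermoTable(specificHeat(w, grid))
  expect_equal(selfE$O, tab$Emean, tolerance = 1e-6)

  # level occupancy against the Boltzmann closed form
  occ <- reweightObservable(lapply(E, function(e)
    data.frame(E = e, O = as.numeric(e > 0))), w, grid)
  pRef <- exp(-1.5 / grid) / (1 + exp(-1.5 / grid))
  expect_lt(max(abs(occ$O - pRef)), 0.02)

  expect_error(reweightObservable(
    list(data.frame(E = 1, O = NA)), w, grid))
})

test_that("transition detection finds constructed peaks and nothing else", {
  grid <- seq(0.4, 0.9, by = 0.005)
  mkCurve <- function(y) new("ThermoCurve",
    curve = data.frame(T = grid, Tkelvin = grid * 503, Cv = y),
    kelvinScale = 503)

  bump <- 2 * exp(-(grid - 0.62)^2 / (2 * 0.03^2))
  pk <- findTransitions(mkCurve(bump))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$T, 0.62, tolerance = 0.006)

  # monotone decreasing: the peakless monomer-like shape
  expect_equal(nrow(findTransitions(mkCurve(3 - 2 * grid))), 0)

  two <- exp(-(grid - 0.55)^2 / (2 * 0.02^2)) +
    1.4 * exp(-(grid - 0.75)^2 / (2 * 0.02^2))
  pk2 <- findTransitions(mkCurve(two))
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$T, c(0.55, 0.75), tolerance = 0.006)
})

test_that("peaks are assigned to the steepest matching observable", {
  grid <- seq(0.4, 0.9, by = 0.005)
  sig <- function(c) 1 / (1 + exp((grid - c) / 0.01))
  curve <- new("ThermoCurve",
    curve = data.frame(T = grid, Tkelvin = grid * 503,
                       Cv = exp(-(grid - 0.55)^2 / 5e-4) +
                            exp(-(grid - 0.75)^2 / 5e-4)),
    kelvinScale = 503)
  pk <- findTransitions(curve)
  obs <- list(contacts = data.frame(T = grid, O = sig(0.55)),
              rmsd = data.frame(T = grid, O = 3 - 2 * sig(0.75)))
  lab <- assignTransitions(pk, obs)
  expect_equal(lab$label, c("contacts", "rmsd"))

  flat <- assignTransitions(pk, list(flat = data.frame(T = grid, O = 1)))
  expect_true(all(flat$label == "unassigned"))
  expect_error(assignTransitions(pk, list()))
})

test_that("reduced temperatures convert to Kelvin by the 5.03e2 scale", {
  expect_equal(reducedToKelvin(1), 503)
  expect_equal(reducedToKelvin(0.575), 289.2, tolerance = 1e-3)  # ~290 K
  expect_equal(reducedToKelvin(0.6), 301.8, tolerance = 1e-3)    # ~300 K
  expect_error(reducedToKelvin(-0.1))
})

test_that("the full REX -> WHAM chain recovers the dimer's analytic Cv peak", {
  toy <- makeToySystem("square_well_dimer", eps = 2.2)
  lad <- replicaLadder(seq(0.5, 0.675, length.out = 8),
                       exchangePeriod = 500)
  rex <- runREX(toy$system, lad, 4e4, seed = 211, sampleInterval = 100)
  es <- energySamples(rex)
  w <- solveWham(energyHistogramSet(es, temperatures(rex)))
  grid <- seq(0.5, 0.675, by = 0.005)
  tab <- thermoTable(specificHeat(w, grid))
  ref <- toy$reference$Cv(grid)
  expect_lt(abs(grid[which.max(tab$Cv)] - grid[which.max(ref)]),
            2 * 0.005 + 1e-12)
})
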