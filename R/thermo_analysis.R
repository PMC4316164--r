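# WHAM combination of multi-temperature samples, specific heat,
# reweighted observables, transition detection and unit conversion.

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Bin multi-temperature energy samples on a common grid
#'
#' @param samples list of numeric vectors (potential energies, kcal/mol),
#'   one per temperature, burn-in already removed.
#' @param temperatures reduced temperatures, same order.
#' @param binWidth bin width in kcal/mol; by default Freedman-Diaconis on
#'   the pooled samples.
#' @return an \linkS4class{EnergyHistogramSet}.
#' @export
energyHistogramSet <- function(samples, temperatures, binWidth = NULL) {
  stopifnot(length(samples) == length(temperatures))
  if (any(vapply(samples, length, integer(1)) < 1))
    stop("every temperature needs at least one retained sample")
  pooled <- unlist(samples)
  if (is.null(binWidth)) {
    binWidth <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
    if (binWidth <= 0)
      binWidth <- max(diff(range(pooled)) / 50, 1e-8)
  }
  lo <- min(pooled) - binWidth / 2
  nb <- max(1L, ceiling((max(pooled) - lo) / binWidth))
  breaks <- lo + binWidth * (0:nb)
  counts <- vapply(samples, function(s)
    tabulate(findInterval(s, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = nb),
    numeric(nb))
  counts <- matrix(counts, nrow = nb)
  new("EnergyHistogramSet", temperatures = as.numeric(temperatures),
      counts = counts, binMid = (breaks[-1] + breaks[-(nb + 1)]) / 2,
      binWidth = binWidth,
      nSamples = vapply(samples, length, integer(1)) + 0)
}

#' Solve the WHAM equations
#'
#' Fixed-point iteration of the standard weighted-histogram equations:
#' the density of states is
#' \code{Omega(E) = sum_k H_k(E) / sum_k N_k exp(f_k - E / T_k)} and the
#' dimensionless free energies satisfy
#' \code{f_k = -log sum_E Omega(E) exp(-E / T_k)}, iterated until the
#' largest free-energy change drops below \code{tol}.  f of the first
#' temperature is anchored at zero.
#'
#' @param h an \linkS4class{EnergyHistogramSet}.
#' @param tol convergence tolerance on f (default 1e-7).
#' @param maxIter iteration cap (default 1e5).
#' @return a \linkS4class{WhamSolution}.
#' @export
solveWham <- function(h, tol = 1e-7, maxIter = 1e5) {
  stopifnot(is(h, "EnergyHistogramSet"))
  K <- length(h@temperatures)
  beta <- 1 / h@temperatures
  occupied <- h@counts > 0

  # adjacent-temperature histograms must overlap
  if (K > 1) for (k in seq_len(K - 1)) {
    if (!any(occupied[, k] & occupied[, k + 1]))
      stop(sprintf(
        "histograms at T = %.4g and T = %.4g share no occupied bin: no overlap",
        h@temperatures[k], h@temperatures[k + 1]))
  }

  keep <- rowSums(h@counts) > 0
  E <- h@binMid[keep]
  H <- h@counts[keep, , drop = FALSE]
  logHtot <- log(rowSums(H))
  logN <- log(h@nSamples)

  f <- rep(0, K)
  iter <- 0; resid <- Inf
  repeat {
    iter <- iter + 1
    # log denominator per bin: logsumexp_k(log N_k + f_k - beta_k E)
    M <- outer(E, beta, function(e, b) -b * e)
    M <- sweep(M, 2, logN + f, "+")
    mmax <- apply(M, 1, max)
    logDen <- mmax + log(rowSums(exp(M - mmax)))
    logOmega <- logHtot - logDen
    fNew <- vapply(seq_len(K), function(k)
      -.logsumexp(logOmega - beta[k] * E), numeric(1))
    fNew <- fNew - fNew[1]
    resid <- max(abs(fNew - f))
    f <- fNew
    if (resid < tol || iter >= maxIter) break
  }

  lo <- rep(-Inf, length(keep)); lo[keep] <- logOmega
  new("WhamSolution", f = f, logOmega = lo, binMid = h@binMid,
      binWidth = h@binWidth, temperatures = h@temperatures,
      tol = tol, iterations = iter + 0, converged = resid < tol,
      residual = resid)
}

.canonicalMoments <- function(w, Tval) {
  keep <- is.finite(w@logOmega)
  E <- w@binMid[keep]; lo <- w@logOmega[keep]
  lw <- lo - E / Tval
  m <- max(lw)
  p <- exp(lw - m); p <- p / sum(p)
  E1 <- sum(p * E)
  E2 <- sum(p * E^2)
  c(E1 = E1, var = max(E2 - E1^2, 0))
}

#' Specific heat from a WHAM solution
#'
#' Canonical averages from Boltzmann sums over the density of states;
#' \code{Cv(T) = (<E^2> - <E>^2) / T^2} with k_B = 1.  The returned curve
#' also carries \code{<E>(T)} and the Kelvin equivalent of the grid
#' (scale 5.03e2).
#'
#' @param w a converged \linkS4class{WhamSolution}.
#' @param Tgrid strictly increasing reduced temperatures, all > 0.
#' @return a \linkS4class{ThermoCurve}.
#' @export
specificHeat <- function(w, Tgrid) {
  stopifnot(is(w, "WhamSolution"))
  if (any(Tgrid <= 0)) stop("temperatures on the grid must be > 0")
  mom <- t(vapply(Tgrid, function(Tv) .canonicalMoments(w, Tv), numeric(2)))
  new("ThermoCurve",
      curve = data.frame(T = Tgrid, Tkelvin = reducedToKelvin(Tgrid),
                         Cv = mom[, "var"] / Tgrid^2, Emean = mom[, "E1"]),
      kelvinScale = 503)
}

#' WHAM-reweighted canonical average of an observable
#'
#' @param samples list (one per simulated temperature) of data.frames with
#'   columns \code{E} and \code{O}.
#' @param w the \linkS4class{WhamSolution} for the same temperatures.
#' @param Tgrid evaluation temperatures.
#' @return data.frame(T, O).
#' @export
reweightObservable <- function(samples, w, Tgrid) {
  stopifnot(length(samples) == length(w@temperatures))
  for (s in samples) {
    if (!all(c("E", "O") %in% names(s))) stop("samples need columns E and O")
    if (anyNA(s$O) || anyNA(s$E)) stop("missing E or O values")
  }
  E <- unlist(lapply(samples, function(s) s$E))
  O <- unlist(lapply(samples, function(s) s$O))
  beta <- 1 / w@temperatures
  logN <- log(vapply(samples, nrow, integer(1)))
  # per-sample log denominator (independent of target T)
  M <- outer(E, beta, function(e, b) -b * e)
  M <- sweep(M, 2, logN + w@f, "+")
  mmax <- apply(M, 1, max)
  logDen <- mmax + log(rowSums(exp(M - mmax)))
  out <- vapply(Tgrid, function(Tv) {
    lw <- -E / Tv - logDen
    m <- max(lw)
    wt <- exp(lw - m)
    sum(wt * O) / sum(wt)
  }, numeric(1))
  data.frame(T = Tgrid, O = out)
}

#' Locate cooperative transitions as specific-heat peaks
#'
#' Local maxima of Cv(T) whose topographic prominence exceeds
#' \code{minProminence} (default 5 percent of the curve's dynamic range),
#' in ascending temperature order.  A monotone or featureless curve
#' yields an empty result.
#'
#' @param curve a \linkS4class{ThermoCurve} (>= 5 grid points).
#' @return data.frame(T, Cv, prominence), possibly with zero rows.
#' @export
findTransitions <- function(curve, minProminence = NULL) {
  stopifnot(is(curve, "ThermoCurve"))
  tab <- curve@curve
  if (nrow(tab) < 5) stop("need at least 5 grid points")
  y <- tab$Cv
  if (is.null(minProminence)) minProminence <- 0.05 * diff(range(y))
  n <- length(y)
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(peaks))
    return(data.frame(T = numeric(0), Cv = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(peaks, function(p) {
    left <- y[seq_len(p - 1)]
    hi <- which(left > y[p])
    lmin <- if (length(hi)) min(y[(max(hi) + 1):(p - 1)]) else min(left)
    right <- y[(p + 1):n]
    hi <- which(right > y[p])
    rmin <- if (length(hi)) min(right[seq_len(min(hi) - 1)]) else min(right)
    y[p] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= minProminence
  data.frame(T = tab$T[peaks[keep]], Cv = y[peaks[keep]],
             prominence = prom[keep])
}

#' Assign transitions to the observable that changes most steeply there
#'
#' Each specific-heat peak is labelled with the observable (for example
#' inter-molecular contact count, backbone RMSD or helix content) whose
#' maximal \code{|dO/dT|} lies nearest the peak temperature; a peak with
#' only flat observables is labelled "unassigned".
#'
#' @param peaks data.frame from \code{\link{findTransitions}}.
#' @param observables named list of data.frames (T, O) on a common grid.
#' @return the peaks data.frame with columns \code{label} and
#'   \code{slopeT} added.
#' @export
assignTransitions <- function(peaks, observables) {
  if (!length(observables)) stop("no observable provided")
  steep <- lapply(observables, function(ob) {
    dT <- diff(ob$T)
    slope <- abs(diff(ob$O)) / dT
    mid <- (ob$T[-1] + ob$T[-nrow(ob)]) / 2
    flat <- diff(range(ob$O)) < 1e-12 || max(slope) < 1e-12
    list(Tmax = if (flat) NA_real_ else mid[which.max(slope)], flat = flat)
  })
  peaks$label <- vapply(peaks$T, function(Tp) {
    d <- vapply(steep, function(s)
      if (s$flat) Inf else abs(s$Tmax - Tp), numeric(1))
    if (all(!is.finite(d))) "unassigned" else names(steep)[which.min(d)]
  }, character(1))
  peaks$slopeT <- vapply(peaks$label, function(lb)
    if (lb == "unassigned") NA_real_ else steep[[lb]]$Tmax, numeric(1))
  peaks
}

#' Convert reduced temperature to Kelvin
#'
#' Multiplies by the calibration factor 5.03e2 K per reduced unit, so
#' T = 0.575 corresponds to ~290 K and T = 0.6 to ~300 K.
#' @export
reducedToKelvin <- function(T) {
  if (any(T < 0)) stop("negative temperature")
  T * 503
}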