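#' @include AllClasses.R
NULL

#' Constants of the finite-chain Flory radius-of-gyration relation
#'
#' `b` is the prefactor (0.55 nm, the geometric mean of a ~0.40 nm
#' persistence length and the 0.38 nm C-alpha spacing), `gamma` (1.1615)
#' derives from the exponent of the Schultz distribution for equilibrium
#' chain length, and `nuThreshold` (0.5) marks the coil-to-globule
#' transition for finite disordered heteropolymers.
#'
#' @param b prefactor, nm.
#' @param gamma dimensionless shape constant.
#' @param nuThreshold exponent value defining the theta temperature.
#' @return list(b, gamma, nuThreshold).
#' @export
floryConstants <- function(b = 0.55, gamma = 1.1615, nuThreshold = 0.5) {
  list(b = b, gamma = gamma, nuThreshold = nuThreshold)
}

#' Radius of gyration implied by a Flory exponent
#'
#' `S = sqrt( gamma (gamma + 1) / (2 (gamma + 2 nu)(gamma + 2 nu + 1)) )
#'  * b * N^nu` for a chain with `N` bonds.
#'
#' @param nu scaling exponent, in (0, 1).
#' @param N number of bonds (chain length - 1).
#' @param const constants from [floryConstants()].
#' @return radius of gyration, nm.
#' @export
rgFromNu <- function(nu, N, const = floryConstants()) {
  if (any(nu <= 0 | nu >= 1)) stop("nu must lie in (0, 1)", call. = FALSE)
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  g <- const$gamma
  sqrt(g * (g + 1) / (2 * (g + 2 * nu) * (g + 2 * nu + 1))) *
    const$b * N^nu
}

#' Flory exponent implied by a radius of gyration
#'
#' Inverts [rgFromNu()] by bracketed root-finding on nu in (0.05, 0.95);
#' the relation is strictly increasing in nu for N >= 2, so the root is
#' unique. Round-trips with [rgFromNu()] to better than 1e-8.
#'
#' @param S radius of gyration, nm.
#' @param N number of bonds.
#' @param const constants from [floryConstants()].
#' @return the scaling exponent nu.
#' @export
nuFromRg <- function(S, N, const = floryConstants()) {
  lo <- 0.05; hi <- 0.95
  Slo <- rgFromNu(lo, N, const); Shi <- rgFromNu(hi, N, const)
  if (S < Slo || S > Shi)
    stop(sprintf(
      "Rg %.4g nm outside the attainable range [%.4g, %.4g] nm for N = %d",
      S, Slo, Shi, as.integer(N)), call. = FALSE)
  uniroot(function(nu) rgFromNu(nu, N, const) - S, c(lo, hi),
          tol = 1e-12)$root
}

#' Build a NuSeries from per-temperature radii of gyration
#'
#' Converts mean Rg values (with optional block-derived standard errors) to
#' Flory exponents at each temperature.
#'
#' @param temperatures K, strictly increasing.
#' @param rg mean radius of gyration per temperature, nm.
#' @param N number of bonds of the chain.
#' @param se standard errors on Rg, nm (propagated numerically; NA allowed).
#' @param const constants from [floryConstants()].
#' @return a [NuSeries-class].
#' @export
nuSeries <- function(temperatures, rg, N, se = rep(NA_real_, length(rg)),
                     const = floryConstants()) {
  nu <- vapply(rg, nuFromRg, numeric(1), N = N, const = const)
  nuSe <- vapply(seq_along(rg), function(i) {
    if (is.na(se[i])) return(NA_real_)
    h <- se[i]
    abs(nuFromRg(min(rg[i] + h, rgFromNu(0.949, N, const)), N, const) -
          nuFromRg(max(rg[i] - h, rgFromNu(0.051, N, const)), N, const)) / 2
  }, numeric(1))
  new("NuSeries", temperatures = as.numeric(temperatures), nu = nu,
      se = nuSe)
}

#' Theta (coil-to-globule) temperature from a Flory-exponent series
#'
#' Linearly interpolates the temperature at which nu crosses the threshold
#' (0.5 by default). Returns `NA` when there is no crossing. When several
#' crossings exist the lowest-temperature one is returned and the result
#' carries `attr(, "multiple") = TRUE` with a warning. The result carries
#' `attr(, "transition")`: "LCST-like" when nu decreases with T, "UCST-like"
#' when it increases.
#'
#' @param series a [NuSeries-class] (>= 2 temperatures).
#' @param const constants from [floryConstants()].
#' @return theta temperature in K, or `NA_real_` when nu never crosses.
#' @export
thetaTemperature <- function(series, const = floryConstants()) {
  stopifnot(is(series, "NuSeries"))
  Tv <- series@temperatures; nu <- series@nu
  if (length(Tv) < 2) stop("need at least 2 temperatures", call. = FALSE)
  thr <- const$nuThreshold
  trend <- unname(coef(lm(nu ~ Tv))[2])
  kind <- if (trend < 0) "LCST-like" else "UCST-like"
  s <- nu - thr
  cross <- which(s[-length(s)] * s[-1] < 0 | s[-length(s)] == 0)
  if (s[length(s)] == 0) cross <- c(cross, length(s))
  cross <- unique(cross)
  if (!length(cross)) {
    out <- NA_real_
    attr(out, "transition") <- kind
    return(out)
  }
  i <- cross[1]
  out <- if (s[i] == 0) Tv[i] else
    Tv[i] + (thr - nu[i]) * (Tv[i + 1] - Tv[i]) / (nu[i + 1] - nu[i])
  if (length(cross) > 1) {
    warning("multiple nu = ", thr,
            " crossings; returning the lowest-temperature one")
    attr(out, "multiple") <- TRUE
  }
  attr(out, "transition") <- kind
  out
}

#' CLOUD-FIT: cloud point from a temperature scan of slab density profiles
#'
#' Finite-size density fluctuations make condensate formation visible as a
#' sharp spike in the z-density profile of a slab simulated at the
#' experimental concentration. Scanning profiles in ascending temperature,
#' the cloud point is the first temperature whose profile exhibits such a
#' spike: by default, a maximum bin density of at least `spikeFactor` times
#' the median bin density, persisting in at least `persistence` consecutive
#' stored frames.
#'
#' @param profiles list of [DensityProfile-class], strictly ascending in
#'   temperature and sharing the same binning.
#' @param spikeFactor detection threshold on max/median (default 3).
#' @param persistence required consecutive spiking frames (default 2).
#' @return cloud-point temperature in K, or `NA_real_` when no profile
#'   spikes. A cloud point at the lowest scanned temperature carries a
#'   boundary warning (the true onset may lie below the scan).
#' @export
cloudFit <- function(profiles, spikeFactor = 3, persistence = 2) {
  if (!length(profiles)) stop("no profiles supplied", call. = FALSE)
  temps <- vapply(profiles, temperature, numeric(1))
  if (any(diff(temps) <= 0))
    stop("profiles must be strictly ascending in temperature",
         call. = FALSE)
  bins <- profiles[[1]]@binCenters
  for (p in profiles)
    if (length(p@binCenters) != length(bins) ||
        max(abs(p@binCenters - bins)) > 1e-6)
      stop("profiles must share identical binning", call. = FALSE)
  spikes <- function(p) {
    apply(p@densities, 1, function(d) {
      md <- median(d)
      md > 0 && max(d) >= spikeFactor * md
    })
  }
  hasSpike <- vapply(profiles, function(p) {
    s <- spikes(p)
    if (length(s) < persistence) return(all(s) && length(s) > 0)
    r <- rle(s)
    any(r$values & r$lengths >= persistence)
  }, logical(1))
  if (!any(hasSpike)) return(NA_real_)
  idx <- which(hasSpike)[1]
  if (idx == 1L)
    warning("spike already present at the lowest scanned temperature; ",
            "the cloud point may lie below the scan range")
  temps[idx]
}

#' Coexisting dilute and dense densities from a slab profile
#'
#' Time-averages the profile, identifies the dense central region by
#' thresholding midway between the two plateau levels, and averages the
#' plateau interiors after excluding an interfacial margin (default 10% of
#' the dense-slab width on each side, mirrored for the dilute region).
#'
#' @param profile a [DensityProfile-class] with a two-plateau structure.
#' @param margin interfacial exclusion as a fraction of the dense-region
#'   width (default 0.1).
#' @param minContrast minimum (max - min)/max density contrast below which
#'   the profile is declared single-phase (default 0.2).
#' @return named numeric c(rhoDilute, rhoDense) in g/cm^3.
#' @export
coexistenceDensities <- function(profile, margin = 0.1, minContrast = 0.2) {
  d <- profileMean(profile)
  nb <- length(d)
  if (nb < 10) stop("profile too coarse for plateau detection",
                    call. = FALSE)
  if ((max(d) - min(d)) < minContrast * max(d))
    stop("no two-plateau structure detected (single phase?)",
         call. = FALSE)
  # center the dense region: rotate so the density maximum sits mid-array
  shift <- round(nb / 2) - which.max(d)
  dc <- d[((seq_len(nb) - 1 - shift) %% nb) + 1]
  thr <- (max(dc) + min(dc)) / 2
  dense <- which(dc >= thr)
  # dense region must be one contiguous block after centering
  if (any(diff(dense) != 1))
    dense <- seq(min(dense), max(dense))
  w <- length(dense)
  ex <- max(1L, ceiling(margin * w))
  denseCore <- dense[(ex + 1):(w - ex)]
  if (!length(denseCore)) denseCore <- dense
  dilute <- setdiff(seq_len(nb), seq(min(dense) - ex, max(dense) + ex))
  dilute <- dilute[dilute >= 1 & dilute <= nb]
  if (!length(dilute))
    stop("no dilute region left after interfacial exclusion", call. = FALSE)
  out <- c(rhoDilute = mean(dc[dilute]), rhoDense = mean(dc[denseCore]))
  if (out["rhoDense"] <= out["rhoDilute"])
    stop("plateau detection failed: dense density not above dilute",
         call. = FALSE)
  out
}

#' Assemble a binodal dataset from coexistence points
#'
#' @param T temperatures, K.
#' @param rhoDilute,rhoDense coexisting densities, g/cm^3.
#' @param seDilute,seDense standard errors (optional).
#' @param mode "LCST" or "UCST"; `NULL` infers it from the sign of the
#'   temperature trend of the density gap (widening gap with T means LCST).
#' @return an unfitted [BinodalDataset-class].
#' @export
binodalDataset <- function(T, rhoDilute, rhoDense,
                           seDilute = rep(NA_real_, length(T)),
                           seDense = rep(NA_real_, length(T)),
                           mode = NULL) {
  if (is.null(mode)) {
    gap <- rhoDense - rhoDilute
    mode <- if (unname(coef(lm(gap ~ T))[2]) > 0) "LCST" else "UCST"
  }
  o <- order(T)
  new("BinodalDataset",
      points = data.frame(T = T[o], rhoDilute = rhoDilute[o],
                          rhoDense = rhoDense[o], seDilute = seDilute[o],
                          seDense = seDense[o]),
      mode = mode, Tc = NA_real_, rhoc = NA_real_, fit = list())
}

#' Fit the critical point by the laws of coexistence densities and
#' rectilinear diameters
#'
#' Simultaneous least squares of
#' `rhoDense - rhoDilute = A |T - Tc|^beta` (law of coexistence densities)
#' and `(rhoDense + rhoDilute)/2 = rhoc + s |T - Tc|` (law of rectilinear
#' diameters), with the 3D-Ising exponent beta = 0.325 by default. For LCST
#' data all points lie above Tc; for UCST below. Initial values come from
#' the linearization `(drho)^(1/beta) = a + b T`, refined with
#' Levenberg-Marquardt on the joint residuals.
#'
#' @param dataset a [BinodalDataset-class] with >= 3 points.
#' @param beta critical exponent of the coexistence law (default 0.325).
#' @return the dataset with `Tc`, `rhoc` and fit diagnostics filled in;
#'   retrieve the critical point with [criticalPoint()].
#' @export
fitBinodal <- function(dataset, beta = 0.325) {
  stopifnot(is(dataset, "BinodalDataset"))
  pts <- dataset@points
  if (nrow(pts) < 3) stop("need at least 3 coexistence points",
                          call. = FALSE)
  sgn <- if (dataset@mode == "LCST") +1 else -1
  gap <- pts$rhoDense - pts$rhoDilute
  mid <- (pts$rhoDense + pts$rhoDilute) / 2
  # linearized initialization: gap^(1/beta) = a + b*T crosses zero at Tc
  lf <- lm(I(gap^(1 / beta)) ~ T, data = pts)
  Tc0 <- -coef(lf)[1] / coef(lf)[2]
  # guard: Tc must sit on the correct side of the data
  if (sgn > 0 && Tc0 >= min(pts$T)) Tc0 <- min(pts$T) - 1
  if (sgn < 0 && Tc0 <= max(pts$T)) Tc0 <- max(pts$T) + 1
  A0 <- mean(gap / abs(pts$T - Tc0)^beta)
  lr <- lm(mid ~ I(abs(T - Tc0)), data = pts)
  resFun <- function(p) {
    Tc <- p[1]; rhoc <- p[2]; A <- p[3]; s <- p[4]
    dT <- sgn * (pts$T - Tc)
    if (any(dT <= 0)) return(rep(1e3, 2 * nrow(pts)))
    c(gap - A * dT^beta, mid - (rhoc + s * dT))
  }
  start <- c(Tc = unname(Tc0), rhoc = unname(coef(lr)[1]), A = A0,
             s = unname(coef(lr)[2]))
  nls <- minpack.lm::nls.lm(par = start, fn = resFun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  if (nls$info %in% c(0, 9))
    stop("critical-point fit did not converge: ", nls$message,
         call. = FALSE)
  p <- nls$par
  dataset@Tc <- unname(p[1])
  dataset@rhoc <- unname(p[2])
  dataset@fit <- list(beta = beta, A = unname(p[3]), slope = unname(p[4]),
                      residuals = resFun(p), converged = TRUE,
                      message = nls$message)
  dataset
}

#' Block-averaged mean and standard error of a time series
#'
#' Splits the series into `nBlocks` contiguous, equal blocks (any remainder
#' joins the last block), and reports the mean of the block means and their
#' standard error, `sd(block means)/sqrt(nBlocks)` — the 3-block error
#' convention used for simulation observables.
#'
#' @param series numeric time series.
#' @param nBlocks number of blocks (default 3).
#' @return named numeric c(mean, se).
#' @export
blockStats <- function(series, nBlocks = 3L) {
  n <- length(series)
  if (n < nBlocks) stop("series shorter than the number of blocks",
                        call. = FALSE)
  size <- n %/% nBlocks
  means <- vapply(seq_len(nBlocks), function(b) {
    from <- (b - 1L) * size + 1L
    to <- if (b == nBlocks) n else b * size
    mean(series[from:to])
  }, numeric(1))
  c(mean = mean(means), se = sd(means) / sqrt(nBlocks))
}

#' Experimental cloud point from an absorbance curve
#'
#' The cloud point is the temperature at which transmittance drops to 0.5,
#' i.e. absorbance reaches `-log10(0.5) = 0.30103`. Returns the linear
#' interpolation of the first upward crossing.
#'
#' @param T temperatures, K (ascending).
#' @param absorbance absorbance values at each temperature.
#' @return cloud-point temperature, K. If the curve starts at or above the
#'   threshold, the first temperature is returned with a boundary warning.
#' @export
cloudPointFromAbsorbance <- function(T, absorbance) {
  if (length(T) != length(absorbance) || length(T) < 2)
    stop("need matched T/absorbance vectors of length >= 2", call. = FALSE)
  thr <- -log10(0.5)
  if (absorbance[1] >= thr) {
    warning("absorbance already at/above 0.301 at the first temperature; ",
            "returning the boundary value")
    return(T[1])
  }
  up <- which(absorbance[-length(absorbance)] < thr &
                absorbance[-1] >= thr)
  if (!length(up))
    stop("absorbance never crosses the 0.301 cloud-point threshold",
         call. = FALSE)
  i <- up[1]
  T[i] + (thr - absorbance[i]) * (T[i + 1] - T[i]) /
    (absorbance[i + 1] - absorbance[i])
}

#' RMSD between simulated and experimental cloud points
#'
#' The objective used to rank candidate parameterizations: the root mean
#' squared difference between paired simulated and experimental cloud-point
#' temperatures.
#'
#' @param simulated,experimental equal-length numeric vectors, K.
#' @return RMSD in K.
#' @export
modelRmsd <- function(simulated, experimental) {
  if (length(simulated) != length(experimental) || !length(simulated))
    stop("simulated and experimental lists must have equal length >= 1",
         call. = FALSE)
  sqrt(mean((simulated - experimental)^2))
}
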