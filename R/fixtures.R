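#' @include analysis.R engine.R
NULL

#' Generate an elastin-like polypeptide repeat sequence
#'
#' Concatenates `nRepeats` copies of the 5-residue xPxxG motif with the
#' guest positions set to `guest`; the default motif realization is VPGXG,
#' the classic ELP scaffold.
#'
#' @param guest one-letter code of the guest residue.
#' @param nRepeats number of motif repeats (>= 1).
#' @param motif 5-character motif template containing "X" at the guest
#'   position(s).
#' @return one-letter sequence string of length 5 * nRepeats.
#' @examples
#' elpSequence("V", 4)  # "VPGVGVPGVGVPGVGVPGVG"
#' @export
elpSequence <- function(guest, nRepeats, motif = "VPGXG") {
  if (!is.character(guest) || nchar(guest) != 1L || !guest %in% .aaCodes)
    stop("guest must be a canonical one-letter residue code, got '",
         guest, "'", call. = FALSE)
  if (nRepeats < 1) stop("nRepeats must be >= 1", call. = FALSE)
  unit <- gsub("X", guest, motif, fixed = TRUE)
  .checkSequence(paste(rep(unit, nRepeats), collapse = ""))
}

#' Synthetic slab density profiles with a condensate spike above an onset
#' temperature
#'
#' Generates flat, noisy baseline profiles below `spikeOnsetT` and adds a
#' Gaussian condensate spike of amplitude `spikeFactor` times the baseline
#' at and above the onset — a deterministic stand-in for the finite-size
#' density fluctuations CLOUD-FIT detects.
#'
#' @param TGrid temperatures, K, ascending.
#' @param spikeOnsetT temperature at which the spike appears, K (may lie
#'   beyond the grid, giving all-flat profiles).
#' @param spikeFactor spike amplitude in units of the baseline density
#'   (1.0 means no spike above baseline).
#' @param noiseSd Gaussian noise on bin densities, g/cm^3.
#' @param seed integer seed; identical seeds give identical output.
#' @param baseline dilute-phase density, g/cm^3.
#' @param nBins,nFrames profile geometry.
#' @param boxLength slab z-length, nm.
#' @return list of [DensityProfile-class], one per temperature.
#' @export
syntheticProfiles <- function(TGrid, spikeOnsetT, spikeFactor = 5,
                              noiseSd = 0.002, seed = 1L, baseline = 0.05,
                              nBins = 100L, nFrames = 5L, boxLength = 100) {
  if (any(diff(TGrid) <= 0))
    stop("TGrid must be strictly increasing", call. = FALSE)
  centers <- (seq_len(nBins) - 0.5) * boxLength / nBins
  mid <- boxLength / 2
  width <- boxLength / 40
  .withSeed(seed, lapply(TGrid, function(Tk) {
    dens <- matrix(0, nFrames, nBins)
    for (f in seq_len(nFrames)) {
      d <- baseline + rnorm(nBins, 0, noiseSd)
      if (Tk >= spikeOnsetT && spikeFactor > 1) {
        d <- d + (spikeFactor - 1) * baseline *
          exp(-(centers - mid)^2 / (2 * width^2))
      }
      dens[f, ] <- pmax(d, 0)
    }
    new("DensityProfile", temperature = Tk, binCenters = centers,
        densities = dens, frameTimes = as.numeric(seq_len(nFrames)))
  }))
}

#' Synthetic coexistence points drawn from the critical scaling laws
#'
#' Generates dilute/dense density pairs exactly from the law of coexistence
#' densities, `rhoDense - rhoDilute = amplitude * |T - Tc|^beta`, and the
#' law of rectilinear diameters,
#' `(rhoDense + rhoDilute)/2 = rhoc + slope * |T - Tc|`, plus optional
#' multiplicative Gaussian noise. LCST mode places points above Tc, UCST
#' below.
#'
#' @param Tc critical temperature, K.
#' @param rhoc critical density, g/cm^3.
#' @param amplitude coexistence-law amplitude (> 0).
#' @param slope rectilinear-diameter slope, g/cm^3/K.
#' @param beta critical exponent (default 0.325).
#' @param TOffsets positive temperature offsets |T - Tc|, K.
#' @param noiseSd multiplicative noise level (0 = exact).
#' @param seed integer seed.
#' @param mode "LCST" or "UCST".
#' @return a [BinodalDataset-class].
#' @export
syntheticBinodal <- function(Tc = 300, rhoc = 0.3, amplitude = 0.08,
                             slope = 0.002, beta = 0.325,
                             TOffsets = c(5, 10, 15, 20, 25, 30),
                             noiseSd = 0, seed = 1L, mode = "LCST") {
  if (amplitude <= 0)
    stop("amplitude must be > 0 (coincident arms are degenerate)",
         call. = FALSE)
  if (any(TOffsets <= 0)) stop("TOffsets must be > 0", call. = FALSE)
  sgn <- if (mode == "LCST") +1 else -1
  Tv <- Tc + sgn * sort(TOffsets)
  dT <- abs(Tv - Tc)
  gap <- amplitude * dT^beta
  mid <- rhoc + slope * dT
  lo <- mid - gap / 2
  hi <- mid + gap / 2
  if (noiseSd > 0) {
    noise <- .withSeed(seed, matrix(rnorm(2 * length(Tv), 0, noiseSd), ncol = 2))
    lo <- lo * (1 + noise[, 1])
    hi <- hi * (1 + noise[, 2])
  }
  if (any(lo <= 0))
    stop("parameters yield non-positive dilute densities", call. = FALSE)
  if (any(hi <= lo))
    stop("noise collapsed the density gap; reduce noiseSd", call. = FALSE)
  binodalDataset(Tv, lo, hi, mode = mode)
}

#' Synthetic radius-of-gyration curve with a prescribed nu(T) ramp
#'
#' Linearly interpolates the Flory exponent from `nuStart` to `nuEnd` over
#' the temperature grid and converts to Rg through the finite-chain
#' relation, plus optional Gaussian noise. Closing the loop with
#' [nuSeries()] and [thetaTemperature()] recovers the constructed crossing.
#'
#' @param N number of bonds.
#' @param nuStart,nuEnd exponents at the grid ends, in (0.05, 0.95).
#' @param TGrid temperatures, K, ascending.
#' @param noiseSd Gaussian noise on Rg, nm.
#' @param seed integer seed.
#' @param const constants from [floryConstants()].
#' @return data.frame(T, rg, nuTrue).
#' @export
syntheticRgCurve <- function(N, nuStart = 0.6, nuEnd = 0.4,
                             TGrid = seq(280, 370, by = 10), noiseSd = 0,
                             seed = 1L, const = floryConstants()) {
  if (any(c(nuStart, nuEnd) <= 0.05) || any(c(nuStart, nuEnd) >= 0.95))
    stop("nu values must lie in (0.05, 0.95)", call. = FALSE)
  frac <- (TGrid - TGrid[1]) / (TGrid[length(TGrid)] - TGrid[1])
  nuTrue <- nuStart + (nuEnd - nuStart) * frac
  rg <- rgFromNu(nuTrue, N, const)
  if (noiseSd > 0)
    rg <- rg + .withSeed(seed, rnorm(length(rg), 0, noiseSd))
  data.frame(T = TGrid, rg = rg, nuTrue = nuTrue)
}
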