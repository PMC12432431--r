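# Shared helpers: small parameter sets and systems built in code.

# tabulated static permittivity of water (Malmberg & Maryott fit, 0-100 C);
# independent oracle for the dielectric model
waterPermittivityTable <- function(TK) {
  t <- TK - 273.15
  87.740 - 0.40008 * t + 9.398e-4 * t^2 - 1.410e-6 * t^3
}

# parameter set whose nonbonded interactions are switched off entirely:
# bonds-only chains sample ideal-chain statistics
idealChainParams <- function(k = 1920, r0 = 0.381) {
  p <- defaultModelParams(1)
  p$residues$eps <- 0
  p$residues$charge <- 0
  p$functionals$alpha <- 0
  p$electrolyte$c <- c(0, 0)
  p$bond <- list(k = k, r0 = r0)
  p
}

# a small two-bead "dimer" system bound by one harmonic bond, no nonbonded
dimerSystem <- function(temperature = 300, k = 1920, r0 = 0.381,
                        box = 10) {
  p <- idealChainParams(k, r0)
  p$cutoffs$elec <- 1
  buildSingleChain("GG", temperature, box, params = p, seed = 7L)
}

# a system of several non-interacting (bonds-only) chains of n beads each,
# for ideal-chain statistics with replicate averaging
idealChainSystem <- function(n, nChains, box = NULL, temperature = 300,
                             params = idealChainParams(), seed = 1L) {
  ch <- buildChain(strrep("G", n), params)
  if (is.null(box)) box <- max(20, n * 0.45)
  side <- ceiling(sqrt(nChains))
  coords <- withr::with_seed(seed, {
    out <- vector("list", nChains)
    for (i in seq_len(nChains)) {
      ox <- ((i - 1) %% side + 0.5) * box / side
      oy <- ((i - 1) %/% side + 0.5) * box / side
      out[[i]] <- MpipiT:::.growChain(n, params$bond$r0, 0,
                                      c(ox, oy, box / 2), rep(0, 3),
                                      rep(box, 3))
    }
    do.call(rbind, out)
  })
  MpipiT:::.assembleSystem(coords, rep(box, 3), rep(list(ch), nChains),
                           temperature, params)
}

# mean squared Rg over chains and frames, discarding an equilibration span
meanRg2 <- function(traj, discardFrac = 0.25) {
  nc <- length(traj@system@chains)
  vals <- sapply(seq_len(nc), function(ci) {
    rg <- rgSeries(traj, ci)$rg
    keep <- seq(floor(length(rg) * discardFrac) + 1, length(rg))
    rg[keep]^2
  })
  mean(vals)
}

# random canonical-branch pair spec
randomSpec <- function() {
  sigma <- runif(1, 0.4, 0.8)
  pairPotentialSpec(eps = runif(1, 0.05, 1.5), sigma = sigma,
                    mu = runif(1, 1, 4), nu = runif(1, 1, 3),
                    R = 3 * sigma)
}

# random repulsive-branch pair spec
randomRepulsiveSpec <- function() {
  sigma <- runif(1, 0.4, 0.8)
  pairPotentialSpec(eps = -runif(1, 0.05, 1.0), sigma = sigma,
                    mu = runif(1, 1, 4), nu = runif(1, 1, 3),
                    R = 3 * sigma)
}
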