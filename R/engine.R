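#' @include potentials.R sequence.R
NULL

.amu2g <- 1.66053906660e-24
# amu/nm^3 -> g/cm^3
.amuPerNm3ToGcm3 <- .amu2g / 1e-21

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Resolve ntype x ntype pair matrices for the residue types present.
.resolvePairMatrices <- function(codes, temperature, params) {
  nt <- length(codes)
  mk <- function() matrix(0, nt, nt, dimnames = list(codes, codes))
  m <- list(eps = mk(), sigma = mk(), R = mk(), mu = mk(), nu = mk(),
            alpha = mk(), rstar = mk(), cutoff = mk())
  for (a in seq_len(nt)) for (b in a:nt) {
    sp <- resolvePair(temperature, codes[a], codes[b], params)
    set <- function(nm, v) {
      m[[nm]][a, b] <<- v
      m[[nm]][b, a] <<- v
    }
    set("eps", sp@eps); set("sigma", sp@sigma); set("R", sp@R)
    set("mu", sp@mu); set("nu", sp@nu); set("alpha", sp@alphaWF)
    set("rstar", sp@rstar)
    # eps = 0 makes the canonical branch identically zero: drop the pair
    set("cutoff", if (sp@eps == 0) 0 else if (sp@eps > 0) sp@R else
      sp@rstar)
  }
  m
}

.electroAt <- function(temperature, params) {
  eps <- dielectric(temperature, params$solvent)
  kappa <- inverseDebyeLength(temperature, params$electrolyte, eps = eps)
  list(kappa = kappa, coulPref = .coulomb_kcal_nm / eps,
       cutoff = params$cutoffs$elec, eps = eps)
}

.assembleSystem <- function(coords, box, chains, temperature, params) {
  beads <- do.call(rbind, lapply(chains, function(ch) ch@beads))
  codes <- sort(unique(beads$code))
  types <- match(beads$code, codes)
  typeTable <- params$residues[codes, c("code", "mass", "charge", "sigma")]
  rownames(typeTable) <- NULL
  # wrap into box
  for (d in 1:3) coords[, d] <- coords[, d] %% box[d]
  new("SimSystem", coordinates = coords, box = box, chains = chains,
      chainIndex = rep(seq_along(chains),
                       vapply(chains, beadCount, integer(1))),
      types = as.integer(types), typeTable = typeTable,
      temperature = temperature,
      pair = .resolvePairMatrices(codes, temperature, params),
      electro = .electroAt(temperature, params))
}

.chainBondArrays <- function(system) {
  off <- 0L
  bi <- integer(0); bj <- integer(0); bk <- numeric(0); br0 <- numeric(0)
  for (ch in system@chains) {
    if (bondCount(ch)) {
      bi <- c(bi, ch@bonds$i + off)
      bj <- c(bj, ch@bonds$j + off)
      bk <- c(bk, ch@bonds$k)
      br0 <- c(br0, ch@bonds$r0)
    }
    off <- off + beadCount(ch)
  }
  list(i = bi, j = bj, k = bk, r0 = br0)
}

.beadVectors <- function(system) {
  beads <- do.call(rbind, lapply(system@chains, function(ch) ch@beads))
  list(mass = beads$mass, charge = beads$charge)
}

# compact serpentine lattice conformation filling [lower, upper]: bead i+1
# is always one lattice spacing from bead i, and all pair distances are at
# least the spacing, so dense cells pack without overlaps
.serpentineChain <- function(n, lower, upper, jitter = 0.01) {
  span <- upper - lower
  nx <- max(2L, ceiling(n^(1 / 3)))
  ny <- max(1L, ceiling(sqrt(n / nx)))
  nz <- ceiling(n / (nx * ny))
  sp <- span / c(max(nx - 1, 1), max(ny - 1, 1), max(nz - 1, 1))
  pos <- matrix(0, n, 3)
  i <- 1L
  for (iz in seq_len(nz) - 1L) {
    yOrder <- if (iz %% 2L) rev(seq_len(ny) - 1L) else seq_len(ny) - 1L
    for (iy in yOrder) {
      xOrder <- if ((iz + iy) %% 2L) rev(seq_len(nx) - 1L) else
        seq_len(nx) - 1L
      for (ix in xOrder) {
        if (i > n) break
        pos[i, ] <- lower + c(ix, iy, iz) * sp
        i <- i + 1L
      }
      if (i > n) break
    }
    if (i > n) break
  }
  pos + matrix(rnorm(3 * n, 0, jitter), n, 3)
}

# grow one chain as a self-avoiding walk with fixed bond length
.growChain <- function(n, r0, minDist, origin, lower, upper, maxTry = 200L) {
  pos <- matrix(0, n, 3)
  pos[1, ] <- origin
  if (n == 1L) return(pos)
  for (i in 2:n) {
    placed <- FALSE
    for (tr in seq_len(maxTry)) {
      u <- rnorm(3)
      step <- r0 * u / sqrt(sum(u^2))
      cand <- pos[i - 1, ] + step
      cand <- pmin(pmax(cand, lower), upper) # keep inside region
      d2 <- if (i > 2)
        rowSums((pos[seq_len(i - 2), , drop = FALSE] -
                   matrix(cand, i - 2, 3, byrow = TRUE))^2)
      else numeric(0)
      if (!length(d2) || min(d2) > minDist^2) {
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) { # straight-segment fallback
      pos[i, ] <- pmin(pmax(pos[i - 1, ] + c(r0, 0, 0), lower), upper)
    }
  }
  pos
}

#' Build a single-chain simulation system
#'
#' Initializes one chain as a self-avoiding random walk (fixed seed gives
#' identical coordinates) centered in a cubic periodic box, with pair
#' parameters resolved at the requested temperature.
#'
#' @param sequence one-letter residue string.
#' @param temperature simulation temperature, K.
#' @param boxSize cubic box edge, nm; must exceed the chain contour length.
#' @param params model parameter list.
#' @param seed integer seed for the initial conformation.
#' @return a [SimSystem-class].
#' @examples
#' sys <- buildSingleChain(elpSequence("V", 4), 300, 30, seed = 1)
#' @export
buildSingleChain <- function(sequence, temperature, boxSize,
                             params = defaultModelParams(), seed = 1L) {
  chain <- buildChain(sequence, params)
  n <- beadCount(chain)
  contour <- if (n > 1) sum(chain@bonds$r0) else 0
  if (boxSize < contour)
    stop(sprintf(
      "box (%g nm) smaller than fully extended chain (%g nm)",
      boxSize, contour), call. = FALSE)
  minDist <- 0.7 * min(chain@beads$sigma)
  coords <- .withSeed(seed, .growChain(
    n, if (n > 1) chain@bonds$r0[1] else 0.38, minDist,
    origin = rep(boxSize / 2, 3), lower = rep(0, 3), upper = rep(boxSize, 3)))
  .assembleSystem(coords, rep(boxSize, 3), list(chain), temperature, params)
}

#' Build a direct-coexistence slab system
#'
#' Replicates the chain 64 times (4 x 4 x 4) for sequences shorter than 190
#' residues and 27 times (3 x 3 x 3) otherwise, packs the chains into a
#' central dense slab at `denseDensity`, and extends the box z-edge so the
#' overall mass concentration equals `targetConcentration`. A short
#' capped-displacement steepest-descent relaxation removes residual
#' overlaps.
#'
#' @param sequence one-letter residue string.
#' @param targetConcentration overall protein concentration, g/L.
#' @param denseDensity density of the packed slab, g/cm^3 (0.8-1.0, the
#'   compression window used for slab preparation).
#' @param temperature simulation temperature, K.
#' @param params model parameter list.
#' @param seed integer seed for chain placement.
#' @param relax run the overlap-relaxation minimization (default TRUE).
#' @return a [SimSystem-class] with the slab centered in z.
#' @export
buildSlab <- function(sequence, targetConcentration, denseDensity = 0.9,
                      temperature = 300, params = defaultModelParams(),
                      seed = 1L, relax = TRUE) {
  if (denseDensity < 0.8 || denseDensity > 1.0)
    stop("denseDensity must lie in [0.8, 1.0] g/cm^3", call. = FALSE)
  chain <- buildChain(sequence, params)
  len <- beadCount(chain)
  nChains <- if (len < 190L) 64L else 27L
  nSide <- if (nChains == 64L) 4L else 3L
  concDense <- targetConcentration / 1000 # g/cm^3
  if (concDense >= denseDensity)
    stop("target concentration exceeds the dense slab density",
         call. = FALSE)
  massChain <- sum(chain@beads$mass)
  massTot <- nChains * massChain
  vDense <- massTot * .amuPerNm3ToGcm3 / denseDensity # nm^3
  a <- vDense^(1 / 3)                                 # dense cube edge, nm
  lz <- massTot * .amuPerNm3ToGcm3 / concDense / a^2
  cell <- a / nSide
  z0 <- (lz - a) / 2
  coords <- .withSeed(seed, {
    out <- vector("list", nChains)
    idx <- 1L
    pad <- 0.35 * min(chain@beads$sigma) # keep chains off shared cell faces
    for (ix in seq_len(nSide) - 1L) for (iy in seq_len(nSide) - 1L)
      for (iz in seq_len(nSide) - 1L) {
        lower <- c(ix * cell, iy * cell, z0 + iz * cell) + pad
        upper <- lower + cell - 2 * pad
        out[[idx]] <- .serpentineChain(len, lower, upper)
        idx <- idx + 1L
      }
    do.call(rbind, out)
  })
  chains <- rep(list(chain), nChains)
  sys <- .assembleSystem(coords, c(a, a, lz), chains, temperature, params)
  if (relax) {
    bonds <- .chainBondArrays(sys)
    bv <- .beadVectors(sys)
    newPos <- cpp_minimize(sys@coordinates, sys@box, sys@types - 1L,
                           bv$charge, bv$mass, bonds$i - 1L, bonds$j - 1L,
                           bonds$k, bonds$r0, sys@pair,
                           sys@electro$coulPref, sys@electro$kappa,
                           sys@electro$cutoff, 200L, 0.02)
    for (d in 1:3) newPos[, d] <- newPos[, d] %% sys@box[d]
    sys@coordinates <- newPos
    validObject(sys)
  }
  sys
}

#' Total potential energy and forces of a system
#'
#' Evaluates bonded + Wang-Frenkel (both branches) + Yukawa terms, either
#' through the Verlet neighbour list or by an all-pairs sweep (the two are
#' exactly equivalent; the all-pairs path serves as the oracle).
#'
#' @param system a [SimSystem-class].
#' @param neighborList use the Verlet list (default TRUE).
#' @param skin neighbour-list skin, nm.
#' @return list(energy = kcal/mol, forces = N x 3 matrix, kcal/mol/nm).
#' @export
systemForces <- function(system, neighborList = TRUE, skin = 0.3) {
  bonds <- .chainBondArrays(system)
  bv <- .beadVectors(system)
  cpp_compute_forces(system@coordinates, system@box, system@types - 1L,
                     bv$charge, bv$mass, bonds$i - 1L, bonds$j - 1L,
                     bonds$k, bonds$r0, system@pair, system@electro$coulPref,
                     system@electro$kappa, system@electro$cutoff,
                     neighborList, skin)
}

#' Run Langevin dynamics
#'
#' BAOAB-discretized Langevin integration with a Verlet neighbour list.
#' Identical inputs and seed give identical trajectories. With
#' `damping <= 0` the thermostat is disabled and the integrator reduces to
#' velocity Verlet (microcanonical).
#'
#' @param system a [SimSystem-class].
#' @param nSteps number of timesteps.
#' @param dt timestep, fs (default 10).
#' @param damping thermostat relaxation time, ps (default 5); `<= 0`
#'   disables the thermostat.
#' @param seed integer seed for initial velocities and the thermostat noise.
#' @param sampleEvery store a frame every this many steps (default 1000).
#' @param neighborList use the Verlet list (default TRUE).
#' @param skin neighbour-list skin, nm.
#' @return a [Trajectory-class]; `thermo(traj)` has per-sample time (ps),
#'   potential and kinetic energy (kcal/mol) and instantaneous temperature
#'   (K).
#' @export
runLangevin <- function(system, nSteps, dt = 10, damping = 5, seed = 1L,
                        sampleEvery = 1000L, neighborList = TRUE,
                        skin = 0.3) {
  stopifnot(is(system, "SimSystem"))
  if (dt > 10 + 1e-9)
    warning("timestep above the 10 fs default; integration may be unstable")
  bonds <- .chainBondArrays(system)
  bv <- .beadVectors(system)
  friction <- if (damping > 0) 1 / damping else 0
  res <- cpp_run_langevin(system@coordinates, system@box, system@types - 1L,
                          bv$charge, bv$mass, bonds$i - 1L, bonds$j - 1L,
                          bonds$k, bonds$r0, system@pair,
                          system@electro$coulPref, system@electro$kappa,
                          system@electro$cutoff, as.integer(nSteps),
                          dt / 1000, friction, .kB_kcal * system@temperature,
                          as.integer(seed), as.integer(sampleEvery),
                          neighborList, skin)
  d <- res$dim
  frames <- aperm(array(res$frames, dim = c(3, d[2], d[1])), c(3, 2, 1))
  n <- beadCount(system)
  thermo <- data.frame(time = res$times, pe = res$pe, ke = res$ke,
                       temp = 2 * res$ke / (3 * n * .kB_kcal))
  new("Trajectory", times = res$times, frames = frames, thermo = thermo,
      system = system)
}

#' Per-sample thermodynamic log of a trajectory
#'
#' @param traj a [Trajectory-class].
#' @return data.frame(time, pe, ke, temp).
#' @export
thermo <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  traj@thermo
}

#' Radius-of-gyration time series of one chain
#'
#' Mass-weighted Rg per stored frame. The chain is made whole by walking its
#' bonds with minimum-image displacements, so both wrapped and unwrapped
#' frames are handled.
#'
#' @param traj a [Trajectory-class].
#' @param chainIndex which chain (default 1).
#' @return data.frame(time = ps, rg = nm).
#' @export
rgSeries <- function(traj, chainIndex = 1L) {
  sys <- traj@system
  if (chainIndex < 1L || chainIndex > length(sys@chains))
    stop("chain index out of range", call. = FALSE)
  sel <- which(sys@chainIndex == chainIndex)
  m <- sys@chains[[chainIndex]]@beads$mass
  box <- sys@box
  nf <- dim(traj@frames)[1]
  rg <- numeric(nf)
  for (f in seq_len(nf)) {
    x <- traj@frames[f, sel, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 3)
    # make molecule whole across periodic boundaries
    if (nrow(x) > 1) for (i in 2:nrow(x)) {
      d <- x[i, ] - x[i - 1, ]
      d <- d - box * round(d / box)
      x[i, ] <- x[i - 1, ] + d
    }
    com <- colSums(x * m) / sum(m)
    rg[f] <- sqrt(sum(m * rowSums((x - matrix(com, nrow(x), 3,
                                              byrow = TRUE))^2)) / sum(m))
  }
  data.frame(time = traj@times, rg = rg)
}

#' z-binned mass-density profile of a trajectory
#'
#' Bins bead masses along z per stored frame and converts to g/cm^3,
#' producing the profile CLOUD-FIT and coexistence analysis consume.
#'
#' @param traj a [Trajectory-class].
#' @param binWidth z bin width, nm (default 1).
#' @param from first stored frame to include (default 1; use later values to
#'   discard equilibration).
#' @return a [DensityProfile-class].
#' @export
profileFromTrajectory <- function(traj, binWidth = 1, from = 1L) {
  sys <- traj@system
  lz <- sys@box[3]
  nBins <- max(1L, round(lz / binWidth))
  edges <- seq(0, lz, length.out = nBins + 1L)
  binVol <- sys@box[1] * sys@box[2] * (edges[2] - edges[1]) # nm^3
  mass <- .beadVectors(sys)$mass
  sel <- seq(from, dim(traj@frames)[1])
  dens <- matrix(0, length(sel), nBins)
  for (k in seq_along(sel)) {
    z <- traj@frames[sel[k], , 3] %% lz
    b <- pmin(pmax(findInterval(z, edges, rightmost.closed = TRUE), 1L),
              nBins)
    mz <- vapply(seq_len(nBins), function(i) sum(mass[b == i]), numeric(1))
    dens[k, ] <- mz / binVol * .amuPerNm3ToGcm3
  }
  new("DensityProfile", temperature = sys@temperature,
      binCenters = (edges[-1] + edges[-length(edges)]) / 2,
      densities = dens, frameTimes = traj@times[sel] / 1000)
}
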