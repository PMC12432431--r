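#' @include constants.R
NULL

#' Bead-spring topology of a single coarse-grained protein chain
#'
#' One bead per residue, consecutive beads joined by harmonic bonds. The
#' `beads` slot holds the resolved per-residue parameters (mass, charge,
#' diameter, hydrophobic flag, homotypic well depth); `bonds` holds one row
#' per bond with spring constant `k` (kcal/mol/nm^2) and rest length `r0`
#' (nm).
#'
#' @slot sequence character(1), one-letter residue string.
#' @slot beads data.frame with columns code, mass, charge, sigma,
#'   hydrophobic, eps.
#' @slot bonds data.frame with columns i, j, k, r0 (i, j are 1-based bead
#'   indices of consecutive residues).
#' @exportClass ChainTopology
setClass("ChainTopology",
  representation(sequence = "character", beads = "data.frame",
                 bonds = "data.frame"),
  validity = function(object) {
    n <- nrow(object@beads)
    if (length(object@sequence) != 1L || nchar(object@sequence) != n)
      return("sequence length must equal number of beads")
    if (nrow(object@bonds) != max(n - 1L, 0L))
      return("number of bonds must be number of beads - 1")
    if (n > 1L) {
      if (!all(object@bonds$j == object@bonds$i + 1L))
        return("bonds must connect consecutive residues")
      if (any(object@bonds$r0 <= 0)) return("bond rest length must be > 0")
      if (any(object@bonds$k <= 0)) return("bond spring constant must be > 0")
    }
    if (any(object@beads$mass <= 0)) return("bead masses must be > 0")
    if (any(object@beads$sigma <= 0)) return("bead diameters must be > 0")
    TRUE
  })

#' Fully resolved Wang-Frenkel pair interaction for one bead pair at one
#' temperature
#'
#' `eps` is signed: positive well depths use the canonical attractive form,
#' negative ones the purely repulsive branch truncated at the extremum
#' location `rstar`.
#'
#' @slot eps numeric(1), well depth, kcal/mol (signed).
#' @slot sigma numeric(1), zero-crossing distance, nm.
#' @slot R numeric(1), cutoff where the potential vanishes, nm (3 sigma).
#' @slot mu,nu numeric(1), shape exponents.
#' @slot alphaWF numeric(1), normalizer making the extremum depth equal eps.
#' @slot rstar numeric(1), interior extremum location, nm.
#' @slot repulsive logical(1), TRUE when eps < 0.
#' @exportClass PairPotentialSpec
setClass("PairPotentialSpec",
  representation(eps = "numeric", sigma = "numeric", R = "numeric",
                 mu = "numeric", nu = "numeric", alphaWF = "numeric",
                 rstar = "numeric", repulsive = "logical"),
  validity = function(object) {
    if (object@sigma <= 0) return("sigma must be > 0")
    if (object@R <= object@sigma) return("cutoff R must exceed sigma")
    if (object@alphaWF <= 0) return("alphaWF must be > 0")
    if (object@rstar <= object@sigma || object@rstar >= object@R)
      return("rstar must lie in (sigma, R)")
    if (object@repulsive != (object@eps < 0))
      return("repulsive flag must equal (eps < 0)")
    TRUE
  })

#' A periodic simulation system of coarse-grained chains
#'
#' @slot coordinates N x 3 matrix of bead positions, nm, wrapped into the box.
#' @slot box numeric(3) orthorhombic edge lengths, nm.
#' @slot chains list of [ChainTopology-class].
#' @slot chainIndex integer(N), chain membership of each bead.
#' @slot types integer(N), row index of each bead into `typeTable`.
#' @slot typeTable data.frame of distinct bead types (code, mass, charge,
#'   sigma).
#' @slot temperature numeric(1), K, at which pair parameters were resolved.
#' @slot pair list of ntype x ntype matrices (eps, sigma, alphaWF, mu, nu,
#'   rstar, cutoff) describing resolved Wang-Frenkel interactions.
#' @slot electro list(kappa, coulPref, cutoff) for Yukawa electrostatics
#'   (kappa in 1/nm, coulPref = e^2/(4 pi eps0 eps(T)) in kcal/mol nm).
#' @exportClass SimSystem
setClass("SimSystem",
  representation(coordinates = "matrix", box = "numeric", chains = "list",
                 chainIndex = "integer", types = "integer",
                 typeTable = "data.frame", temperature = "numeric",
                 pair = "list", electro = "list"),
  validity = function(object) {
    n <- nrow(object@coordinates)
    if (ncol(object@coordinates) != 3L) return("coordinates must be N x 3")
    if (length(object@box) != 3L || any(object@box <= 0))
      return("box must be 3 positive edge lengths")
    if (length(object@types) != n || length(object@chainIndex) != n)
      return("types/chainIndex length must match coordinate rows")
    if (n > 0) {
      for (d in 1:3)
        if (any(object@coordinates[, d] < -1e-9 |
                object@coordinates[, d] > object@box[d] + 1e-9))
          return("coordinates must be wrapped into the box")
    }
    cuts <- c(as.numeric(object@pair$cutoff), object@electro$cutoff)
    if (length(cuts) && any(object@box < 2 * max(cuts)))
      return("box edges must exceed twice the largest pair cutoff")
    TRUE
  })

#' A sampled Langevin trajectory
#'
#' @slot times numeric, sample times in ps, strictly increasing.
#' @slot frames 3-d array (frame, bead, xyz) of coordinates, nm (unwrapped;
#'   continuous across periodic images).
#' @slot thermo data.frame(time, pe, ke, temp) in ps / kcal/mol / K.
#' @slot system the [SimSystem-class] the trajectory was generated from.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(times = "numeric", frames = "array", thermo = "data.frame",
                 system = "SimSystem"),
  validity = function(object) {
    if (length(dim(object@frames)) != 3L) return("frames must be 3-d array")
    if (dim(object@frames)[1] != length(object@times))
      return("frame count must match times")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
      return("times must be strictly increasing")
    TRUE
  })

#' A z-binned mass-density profile of a slab system at one temperature
#'
#' @slot temperature numeric(1), K.
#' @slot binCenters numeric, uniform z-bin centers, nm.
#' @slot densities nFrames x nBins matrix, g/cm^3.
#' @slot frameTimes numeric(nFrames), ns.
#' @exportClass DensityProfile
setClass("DensityProfile",
  representation(temperature = "numeric", binCenters = "numeric",
                 densities = "matrix", frameTimes = "numeric"),
  validity = function(object) {
    if (ncol(object@densities) != length(object@binCenters))
      return("density columns must match bin centers")
    if (nrow(object@densities) != length(object@frameTimes))
      return("density rows must match frame times")
    if (any(object@densities < 0)) return("densities must be >= 0")
    if (length(object@binCenters) > 2) {
      w <- diff(object@binCenters)
      if (max(abs(w - w[1])) > 1e-6 * abs(w[1]))
        return("bins must be uniform")
    }
    TRUE
  })

#' Flory exponent estimates across temperature
#'
#' @slot temperatures numeric, K, strictly increasing.
#' @slot nu numeric, estimated scaling exponents, in (0, 1).
#' @slot se numeric, standard errors (NA when unknown).
#' @exportClass NuSeries
setClass("NuSeries",
  representation(temperatures = "numeric", nu = "numeric", se = "numeric"),
  validity = function(object) {
    if (length(object@nu) != length(object@temperatures) ||
        length(object@se) != length(object@temperatures))
      return("temperatures, nu and se must have equal length")
    if (length(object@temperatures) > 1 &&
        any(diff(object@temperatures) <= 0))
      return("temperatures must be strictly increasing")
    if (any(object@nu <= 0 | object@nu >= 1)) return("nu must lie in (0, 1)")
    TRUE
  })

#' Per-temperature coexistence densities and the fitted critical point
#'
#' @slot points data.frame(T, rhoDilute, rhoDense, seDilute, seDense) in K
#'   and g/cm^3.
#' @slot mode "LCST" (phase separation above Tc) or "UCST" (below Tc).
#' @slot Tc numeric(1), fitted critical temperature, K (NA before fitting).
#' @slot rhoc numeric(1), fitted critical density, g/cm^3 (NA before fitting).
#' @slot fit list of fit diagnostics (beta used, amplitudes, residuals).
#' @exportClass BinodalDataset
setClass("BinodalDataset",
  representation(points = "data.frame", mode = "character", Tc = "numeric",
                 rhoc = "numeric", fit = "list"),
  validity = function(object) {
    need <- c("T", "rhoDilute", "rhoDense")
    if (!all(need %in% names(object@points)))
      return("points must have columns T, rhoDilute, rhoDense")
    if (!object@mode %in% c("LCST", "UCST"))
      return("mode must be 'LCST' or 'UCST'")
    if (any(object@points$rhoDense <= object@points$rhoDilute))
      return("rhoDense must exceed rhoDilute at every point")
    TRUE
  })
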