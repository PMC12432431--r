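#' @include params.R
NULL

#' Density of air-free water at 1 atm (Kell formulation)
#'
#' Rational-polynomial fit of liquid-water density against temperature,
#' valid over the liquid range; exhibits the density maximum near 4 degrees C.
#'
#' @param T temperature, K (vectorized); must lie in \[273, 373\] K.
#' @return density, g/cm^3.
#' @examples
#' waterDensity(298.15)  # 0.99705
#' @export
waterDensity <- function(T) {
  .checkTemperature(T)
  t <- T - 273.15
  num <- 999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 -
    46.170461e-6 * t^3 + 105.56302e-9 * t^4 - 280.54253e-12 * t^5
  num / (1 + 16.879850e-3 * t) / 1000
}

#' Temperature-scaled dielectric constant of the solvent
#'
#' Static permittivity modelled as `eps(T) = 1 + rho_solv(T) * d(T)` with the
#' Kell water density and a linear solvent-dependent parameter
#' `d(T) = d0 + d1 * T`. The default coefficients reproduce tabulated water
#' permittivity to within 2% over 273-373 K.
#'
#' @param T temperature, K (vectorized).
#' @param solvent list with `d0`, `d1` (per K) and optionally `Trange`;
#'   defaults to the shipped water parameterization.
#' @return dimensionless dielectric constant, > 1 for d > 0.
#' @examples
#' dielectric(298.15)  # ~78.9
#' @export
dielectric <- function(T, solvent = defaultModelParams()$solvent) {
  rng <- if (!is.null(solvent$Trange)) solvent$Trange else
    .validTemperatureRange
  .checkTemperature(T, rng)
  d <- solvent$d0 + solvent$d1 * T
  1 + waterDensity(T) * d
}

#' Inverse Debye screening length
#'
#' `kappa^2 = e^2 / (eps * eps0 * kB * T) * sum_j z_j^2 c_j` with ion
#' concentrations converted from mol/L to number densities. The dielectric
#' constant is taken self-consistently at the same temperature unless given
#' explicitly.
#'
#' @param T temperature, K.
#' @param electrolyte data.frame with columns `z` (valence) and `c` (mol/L).
#' @param eps dielectric constant; default computed from [dielectric()].
#' @param solvent solvent model used when `eps` is NULL.
#' @return kappa in 1/nm (0 for a salt-free system).
#' @examples
#' 1 / inverseDebyeLength(298.15, data.frame(z = c(1, -1), c = c(.15, .15)),
#'                        eps = 78.4)  # ~0.78 nm
#' @export
inverseDebyeLength <- function(T, electrolyte = defaultModelParams()$electrolyte,
                               eps = NULL,
                               solvent = defaultModelParams()$solvent) {
  if (any(electrolyte$c < 0))
    stop("ion concentrations must be >= 0", call. = FALSE)
  if (is.null(eps)) eps <- dielectric(T, solvent)
  if (eps <= 0) stop("dielectric constant must be > 0", call. = FALSE)
  if (T <= 0) stop("temperature must be > 0", call. = FALSE)
  nd <- electrolyte$c * 1000 * .NA_mol          # ions per m^3
  s <- sum(electrolyte$z^2 * nd)
  kappa_m <- sqrt(.e_C^2 / (eps * .eps0 * .kB_J * T) * s)   # 1/m
  kappa_m * 1e-9                                             # 1/nm
}

#' Parabolic temperature functional mu_X(T)
#'
#' `mu_X(T) = a*T^2 + b*T + c`, the per-residue function whose excursion from
#' the reference temperature scales hydrophobic pair energies.
#'
#' @param T temperature, K (vectorized).
#' @param f one row of the functionals table (fields a, b, c), or a list.
#' @return energy, kcal/mol.
#' @export
muT <- function(T, f) {
  if (!all(is.finite(T))) stop("T must be finite", call. = FALSE)
  f$a * T^2 + f$b * T + f$c
}

#' Temperature-dependent Wang-Frenkel well depth for a residue pair
#'
#' For pairs containing at least one hydrophobic residue (A, V, I, L, M) the
#' well depth is
#' `eps_ij(T) = 0.5*[eps_ii + alpha_i*(mu_i(T) - mu_i(Tref))] +
#'  0.5*[eps_jj + alpha_j*(mu_j(T) - mu_j(Tref))]`
#' with Tref = 298.15 K, so at Tref it reduces to the arithmetic mean of the
#' homotypic baseline well depths. Residues without a shipped functional
#' contribute only their static half (alpha = 0). Pairs with no hydrophobic
#' member keep their temperature-independent baseline value at every T: the
#' default baseline is the arithmetic mean of the homotypic well depths,
#' overridable through `params$pairEps` (a named list "X:Y" -> kcal/mol).
#' The result is signed; negative values select the purely repulsive
#' potential branch.
#'
#' @param T temperature, K (vectorized).
#' @param i,j one-letter residue codes.
#' @param params model parameter list.
#' @return well depth, kcal/mol (signed).
#' @examples
#' epsilonPair(298.15, "V", "L")  # mean of the V and L homotypic depths
#' @export
epsilonPair <- function(T, i, j, params = defaultModelParams()) {
  res <- params$residues
  if (!i %in% res$code) stop("residue not parameterized: ", i, call. = FALSE)
  if (!j %in% res$code) stop("residue not parameterized: ", j, call. = FALSE)
  hyd <- res[i, "hydrophobic"] || res[j, "hydrophobic"]
  if (!hyd) {
    return(rep(.baselinePairEps(i, j, params), length(T)))
  }
  half <- function(x) {
    e0 <- res[x, "eps"]
    if (res[x, "hydrophobic"] && !x %in% rownames(params$functionals))
      stop("missing temperature functional for hydrophobic residue ", x,
           call. = FALSE)
    if (x %in% rownames(params$functionals)) {
      f <- params$functionals[x, ]
      0.5 * (e0 + f$alpha * (muT(T, f) - muT(f$Tref, f)))
    } else rep(0.5 * e0, length(T))
  }
  half(i) + half(j)
}

.baselinePairEps <- function(i, j, params) {
  key <- paste(sort(c(i, j)), collapse = ":")
  if (!is.null(params$pairEps) && !is.null(params$pairEps[[key]]))
    return(params$pairEps[[key]])
  mean(params$residues[c(i, j), "eps"])
}

#' Resolve the full pair-potential specification for a residue pair at a
#' temperature
#'
#' Combines the temperature-dependent well depth with Lorentz-style size
#' mixing (`sigma_ij` = mean of diameters, cutoff `R = 3 sigma_ij`) and the
#' configured shape exponents into a [PairPotentialSpec-class] ready for
#' evaluation or tabulated export.
#'
#' @param T temperature, K.
#' @param i,j one-letter residue codes.
#' @param params model parameter list.
#' @return a [PairPotentialSpec-class].
#' @export
resolvePair <- function(T, i, j, params = defaultModelParams()) {
  eps <- epsilonPair(T, i, j, params)
  sig <- mean(params$residues[c(i, j), "sigma"])
  pairPotentialSpec(eps = eps, sigma = sig,
                    mu = params$wf$mu, nu = params$wf$nu,
                    R = params$cutoffs$pairFactor * sig)
}
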