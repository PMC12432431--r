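#' @include AllClasses.R forcefield.R
NULL

#' Wang-Frenkel normalizer alpha
#'
#' The prefactor that makes the magnitude of the interior extremum of the
#' Wang-Frenkel potential equal the well depth:
#' `alpha = 2 nu (R/sigma)^(2 mu) *
#'  [ (2 nu + 1) / (2 nu ((R/sigma)^(2 mu) - 1)) ]^(2 nu + 1)`.
#' Depends only on the ratio R/sigma and the shape exponents.
#'
#' @param sigma zero-crossing distance, nm.
#' @param R cutoff distance, nm (must exceed sigma).
#' @param mu,nu shape exponents (>= 1).
#' @return dimensionless normalizer.
#' @examples
#' wfAlpha(1, 3, 1, 1)  # 18 * (3/16)^3
#' @export
wfAlpha <- function(sigma, R, mu, nu) {
  if (R <= sigma) stop("cutoff R must exceed sigma", call. = FALSE)
  if (mu < 1 || nu < 1) stop("shape exponents must be >= 1", call. = FALSE)
  x <- (R / sigma)^(2 * mu)
  2 * nu * x * ((2 * nu + 1) / (2 * nu * (x - 1)))^(2 * nu + 1)
}

#' Location of the interior extremum of the Wang-Frenkel potential
#'
#' Closed form
#' `r* = R * [ (1 + 2 nu) / (1 + 2 nu (R/sigma)^(2 mu)) ]^(1/(2 mu))`,
#' i.e. the unique stationary point of the canonical potential on
#' (sigma, R). `method = "numeric"` solves d(phi)/dr = 0 by bracketed
#' root-finding instead; the two agree to 1e-10 relative.
#'
#' @param sigma,R,mu,nu Wang-Frenkel shape parameters (see [wfAlpha()]).
#' @param method "analytic" (default) or "numeric".
#' @return r* in nm, with sigma < r* < R.
#' @examples
#' rStar(1, 3, 1, 1)  # 3 * sqrt(3/19)
#' @export
rStar <- function(sigma, R, mu, nu, method = c("analytic", "numeric")) {
  method <- match.arg(method)
  if (R <= sigma) stop("cutoff R must exceed sigma", call. = FALSE)
  if (method == "analytic") {
    x <- (R / sigma)^(2 * mu)
    return(R * ((1 + 2 * nu) / (1 + 2 * nu * x))^(1 / (2 * mu)))
  }
  # stationary-point condition u(w-1) + 2 nu w (u-1) = 0 with
  # u = (sigma/r)^(2mu), w = (R/r)^(2mu); g > 0 at sigma+, g < 0 at R-.
  g <- function(r) {
    u <- (sigma / r)^(2 * mu); w <- (R / r)^(2 * mu)
    u * (w - 1) + 2 * nu * w * (u - 1)
  }
  lo <- sigma * (1 + 1e-12); hi <- R * (1 - 1e-12)
  if (g(lo) <= 0 || g(hi) >= 0)
    stop("failed to bracket the stationary point", call. = FALSE)
  uniroot(g, c(lo, hi), tol = 1e-15)$root
}

#' Construct a resolved pair-potential specification
#'
#' Computes the normalizer and extremum location and flags the repulsive
#' branch for negative well depths.
#'
#' @param eps signed well depth, kcal/mol.
#' @param sigma zero-crossing distance, nm.
#' @param mu,nu shape exponents.
#' @param R cutoff, nm; default 3 sigma.
#' @return a [PairPotentialSpec-class].
#' @export
pairPotentialSpec <- function(eps, sigma, mu = 2, nu = 1, R = 3 * sigma) {
  new("PairPotentialSpec", eps = as.numeric(eps), sigma = as.numeric(sigma),
      R = as.numeric(R), mu = as.numeric(mu), nu = as.numeric(nu),
      alphaWF = wfAlpha(sigma, R, mu, nu),
      rstar = rStar(sigma, R, mu, nu), repulsive = eps < 0)
}

# canonical Wang-Frenkel value for arbitrary signed eps (no cutoff logic)
.wfRaw <- function(r, eps, sigma, R, mu, nu, alpha) {
  u <- (sigma / r)^(2 * mu); w <- (R / r)^(2 * mu)
  eps * alpha * (u - 1) * (w - 1)^(2 * nu)
}

.wfRawDeriv <- function(r, eps, sigma, R, mu, nu, alpha) {
  u <- (sigma / r)^(2 * mu); w <- (R / r)^(2 * mu)
  -(2 * mu * eps * alpha / r) * (w - 1)^(2 * nu - 1) *
    (u * (w - 1) + 2 * nu * w * (u - 1))
}

#' Canonical Wang-Frenkel pair potential
#'
#' `phi(r) = eps * alpha * [(sigma/r)^(2mu) - 1] * [(R/r)^(2mu) - 1]^(2nu)`
#' for r < R and exactly 0 beyond the cutoff. Requires a non-negative well
#' depth; negative well depths must use [repulsiveWF()].
#'
#' @param r distance(s), nm, > 0.
#' @param spec a [PairPotentialSpec-class] with `eps >= 0`.
#' @return energy, kcal/mol.
#' @export
wfPotential <- function(r, spec) {
  if (any(r <= 0)) stop("distance must be > 0", call. = FALSE)
  if (spec@eps < 0)
    stop("canonical branch requires eps >= 0; use repulsiveWF()",
         call. = FALSE)
  out <- numeric(length(r))
  inside <- r < spec@R
  out[inside] <- .wfRaw(r[inside], spec@eps, spec@sigma, spec@R, spec@mu,
                        spec@nu, spec@alphaWF)
  out
}

#' Purely repulsive Wang-Frenkel branch for negative well depths
#'
#' When the temperature scaling drives a pair's well depth negative, the
#' canonical form would become unboundedly attractive at contact. The revised
#' branch `phi(r) = -phi_WF(r) - eps` for r < r*, 0 for r >= r*, is
#' continuous at r*, non-negative everywhere, divergent as r -> 0, and
#' preserves the molecular diameter.
#'
#' @param r distance(s), nm, > 0.
#' @param spec a [PairPotentialSpec-class] with `eps < 0`.
#' @return energy, kcal/mol (>= 0).
#' @export
repulsiveWF <- function(r, spec) {
  if (any(r <= 0)) stop("distance must be > 0", call. = FALSE)
  if (spec@eps >= 0)
    stop("repulsive branch requires eps < 0", call. = FALSE)
  out <- numeric(length(r))
  inside <- r < spec@rstar
  out[inside] <- -.wfRaw(r[inside], spec@eps, spec@sigma, spec@R, spec@mu,
                         spec@nu, spec@alphaWF) - spec@eps
  out
}

#' Evaluate the appropriate Wang-Frenkel branch
#'
#' Dispatches on the sign of the well depth: canonical attractive form for
#' `eps >= 0`, purely repulsive truncated form for `eps < 0`.
#'
#' @param r distance(s), nm.
#' @param spec a [PairPotentialSpec-class].
#' @param deriv when TRUE return d(phi)/dr instead of phi.
#' @return energy (kcal/mol) or its radial derivative (kcal/mol/nm).
#' @export
pairPotential <- function(r, spec, deriv = FALSE) {
  if (any(r <= 0)) stop("distance must be > 0", call. = FALSE)
  out <- numeric(length(r))
  if (spec@eps >= 0) {
    inside <- r < spec@R
    f <- if (deriv) .wfRawDeriv else .wfRaw
    out[inside] <- f(r[inside], spec@eps, spec@sigma, spec@R, spec@mu,
                     spec@nu, spec@alphaWF)
  } else {
    inside <- r < spec@rstar
    if (deriv) {
      out[inside] <- -.wfRawDeriv(r[inside], spec@eps, spec@sigma, spec@R,
                                  spec@mu, spec@nu, spec@alphaWF)
    } else {
      out[inside] <- -.wfRaw(r[inside], spec@eps, spec@sigma, spec@R,
                             spec@mu, spec@nu, spec@alphaWF) - spec@eps
    }
  }
  out
}

#' Yukawa (screened Coulomb) pair potential
#'
#' `phi(r) = q_i q_j e^2 / (4 pi eps0 eps) * exp(-kappa r) / r`, plainly
#' truncated at the cutoff (no shift by default).
#'
#' @param r distance(s), nm, > 0.
#' @param qi,qj charges in elementary-charge units.
#' @param kappa inverse Debye length, 1/nm.
#' @param eps dielectric constant (> 0).
#' @param cutoff truncation distance, nm (default 3.5).
#' @param deriv when TRUE return d(phi)/dr.
#' @return energy, kcal/mol (or derivative, kcal/mol/nm).
#' @export
yukawa <- function(r, qi, qj, kappa, eps, cutoff = 3.5, deriv = FALSE) {
  if (any(r <= 0)) stop("distance must be > 0", call. = FALSE)
  if (eps <= 0) stop("dielectric constant must be > 0", call. = FALSE)
  pref <- .coulomb_kcal_nm * qi * qj / eps
  out <- numeric(length(r))
  inside <- r < cutoff
  ri <- r[inside]
  if (deriv) {
    out[inside] <- -pref * exp(-kappa * ri) * (kappa * ri + 1) / ri^2
  } else {
    out[inside] <- pref * exp(-kappa * ri) / ri
  }
  out
}

#' Sample a pair potential on a distance grid
#'
#' Energies use the branch selected by the sign of the well depth; forces are
#' the analytic radial derivative, `F = -d(phi)/dr`.
#'
#' @param spec a [PairPotentialSpec-class].
#' @param rGrid strictly increasing positive distances, nm.
#' @return data.frame(r, energy, force) in nm, kcal/mol, kcal/mol/nm.
#' @export
pairTable <- function(spec, rGrid) {
  if (!length(rGrid)) stop("distance grid is empty", call. = FALSE)
  if (any(rGrid <= 0) || any(diff(rGrid) <= 0))
    stop("distance grid must be strictly increasing and positive",
         call. = FALSE)
  data.frame(r = rGrid,
             energy = pairPotential(rGrid, spec),
             force = -pairPotential(rGrid, spec, deriv = TRUE))
}
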