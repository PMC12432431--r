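#' @include constants.R
NULL

# Synthetic default force-field parameter set. Masses and charges are
# standard residue values at model pH (~7.4: D/E -1, K/R +1, H fractional);
# sigma are HPS-style literature bead diameters (nm). Homotypic well depths
# (kcal/mol) and the hydrophobic temperature-functional coefficients are
# SYNTHETIC placeholders with realistic magnitudes, shipped because the
# published fitted tables are distributed as supplementary data files, not in
# a journal article body. Replace them with the published tables for
# full-fidelity work (loadModelParams accepts any file in the same layout).
.defaultResidues <- function(hisCharge = 0.375) {
  df <- data.frame(
    code = .aaCodes,
    mass = c(71.0788, 156.1875, 114.1038, 115.0886, 103.1388, 128.1307,
             129.1155, 57.0519, 137.1411, 113.1594, 113.1594, 128.1741,
             131.1926, 147.1766, 97.1167, 87.0782, 101.1051, 186.2132,
             163.1760, 99.1326),
    charge = c(0, 1, 0, -1, 0, 0, -1, 0, hisCharge, 0,
               0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    sigma = c(0.504, 0.656, 0.568, 0.558, 0.548, 0.602, 0.592, 0.450,
              0.608, 0.618, 0.618, 0.636, 0.618, 0.636, 0.556, 0.518,
              0.562, 0.678, 0.646, 0.586),
    eps = c(0.34, 0.45, 0.36, 0.25, 0.44, 0.38, 0.25, 0.29, 0.47, 0.52,
            0.52, 0.23, 0.53, 0.74, 0.41, 0.30, 0.32, 0.87, 0.71, 0.46),
    stringsAsFactors = FALSE)
  df$hydrophobic <- df$code %in% .hydrophobicSet
  rownames(df) <- df$code
  df
}

# Synthetic parabolic mu_X(T) coefficients (kcal/mol basis) for the five
# hydrophobic residues, per model variant. Chosen so alpha * dmu/dT > 0
# around ambient temperature: hydrophobic attraction strengthens on heating,
# the LCST-driving direction. c is arbitrary (only mu(T) - mu(Tref) enters).
.defaultFunctionals <- function(model = 1L) {
  base <- data.frame(
    code = .hydrophobicSet,  # A V I L M
    stringsAsFactors = FALSE)
  if (model == 1L) {         # linear mu(T)
    base$a <- rep(0, 5)
    base$b <- c(0.0030, 0.0038, 0.0046, 0.0046, 0.0042)
    base$c <- rep(-0.5, 5)
    base$alpha <- rep(1.0, 5)
  } else if (model == 2L) {  # upward curvature
    base$a <- rep(4e-6, 5)
    base$b <- c(0.0006, 0.0014, 0.0022, 0.0022, 0.0018)
    base$c <- rep(-0.3, 5)
    base$alpha <- rep(1.0, 5)
  } else if (model == 3L) {  # downward curvature, larger alpha
    base$a <- rep(-3e-6, 5)
    base$b <- c(0.0048, 0.0056, 0.0064, 0.0064, 0.0060)
    base$c <- rep(0.2, 5)
    base$alpha <- rep(1.1, 5)
  } else stop("model must be 1, 2 or 3", call. = FALSE)
  base$Tref <- 298.15
  rownames(base) <- base$code
  base
}

#' Default model parameter set
#'
#' Assembles the full parameter set for one model variant: per-residue bead
#' parameters, hydrophobic temperature functionals, bond constants, global
#' Wang-Frenkel shape exponents, solvent dielectric coefficients and
#' electrolyte composition. The shipped residue well depths and functional
#' coefficients are synthetic defaults (see [loadModelParams()] to supply
#' published tables).
#'
#' @param model integer 1, 2 or 3, the functional-form variant.
#' @param hisCharge histidine charge at model pH (default 0.375 e).
#' @return a list with elements `model`, `provenance`, `residues` (data.frame),
#'   `functionals` (data.frame), `bond` (k kcal/mol/nm^2, r0 nm), `wf`
#'   (mu, nu), `solvent` (d0, d1 per K; Trange K), `electrolyte` (data.frame
#'   z, c mol/L), `cutoffs` (pairFactor, elec nm).
#' @examples
#' p <- defaultModelParams(1)
#' p$residues["V", ]
#' @export
defaultModelParams <- function(model = 1L, hisCharge = 0.375) {
  list(
    model = as.integer(model),
    provenance = "synthetic defaults (not the published fitted tables)",
    residues = .defaultResidues(hisCharge),
    functionals = .defaultFunctionals(as.integer(model)),
    bond = list(k = 1920, r0 = 0.381),
    wf = list(mu = 2, nu = 1),
    solvent = list(d0 = 165.19997772, d1 = -0.2920690248,
                   Trange = c(273, 373)),
    electrolyte = data.frame(z = c(1, -1), c = c(0.15, 0.15)),
    cutoffs = list(pairFactor = 3, elec = 3.5))
}

#' Write a model parameter set to a YAML config file
#'
#' @param params a parameter list as returned by [defaultModelParams()] or
#'   [loadModelParams()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeModelParams <- function(params, path) {
  out <- params
  out$residues <- lapply(seq_len(nrow(params$residues)), function(i)
    as.list(params$residues[i, c("code", "mass", "charge", "sigma",
                                 "eps", "hydrophobic")]))
  out$functionals <- lapply(seq_len(nrow(params$functionals)), function(i)
    as.list(params$functionals[i, c("code", "a", "b", "c", "alpha", "Tref")]))
  out$electrolyte <- lapply(seq_len(nrow(params$electrolyte)), function(i)
    as.list(params$electrolyte[i, c("z", "c")]))
  out$solvent$Trange <- as.numeric(params$solvent$Trange)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Load a model parameter set from a YAML config file
#'
#' The file layout is the one produced by [writeModelParams()]; load-dump-load
#' is the identity.
#'
#' @param path a YAML parameter file, or `NULL` plus `model` to load the
#'   bundled synthetic defaults.
#' @param model when `path` is NULL: which bundled variant (1, 2 or 3).
#' @return a parameter list (see [defaultModelParams()]).
#' @export
loadModelParams <- function(path = NULL, model = 1L) {
  if (is.null(path)) {
    path <- system.file("extdata",
                        sprintf("params_model%d_synthetic.yaml", model),
                        package = "MpipiT")
    if (!nzchar(path)) return(defaultModelParams(model))
  }
  if (!file.exists(path)) stop("parameter file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  res <- do.call(rbind, lapply(raw$residues, function(r)
    data.frame(code = r$code, mass = r$mass, charge = r$charge,
               sigma = r$sigma, eps = r$eps, hydrophobic = r$hydrophobic,
               stringsAsFactors = FALSE)))
  rownames(res) <- res$code
  fun <- do.call(rbind, lapply(raw$functionals, function(r)
    data.frame(code = r$code, a = r$a, b = r$b, c = r$c, alpha = r$alpha,
               Tref = r$Tref, stringsAsFactors = FALSE)))
  rownames(fun) <- fun$code
  ele <- do.call(rbind, lapply(raw$electrolyte, function(r)
    data.frame(z = r$z, c = r$c)))
  .checkResidueTable(res)
  list(model = raw$model, provenance = raw$provenance, residues = res,
       functionals = fun, bond = raw$bond, wf = raw$wf,
       solvent = list(d0 = raw$solvent$d0, d1 = raw$solvent$d1,
                      Trange = as.numeric(raw$solvent$Trange)),
       electrolyte = ele, cutoffs = raw$cutoffs)
}

.checkResidueTable <- function(res) {
  if (!all(.aaCodes %in% res$code))
    stop("residue table is missing canonical residues: ",
         paste(setdiff(.aaCodes, res$code), collapse = ", "), call. = FALSE)
  if (any(res$mass <= 0) || any(res$sigma <= 0))
    stop("residue masses and diameters must be positive", call. = FALSE)
  hyd <- res$code[res$hydrophobic]
  if (!setequal(hyd, .hydrophobicSet))
    stop("hydrophobic flag must mark exactly {A, V, I, L, M}", call. = FALSE)
  invisible(res)
}

#' The hydrophobic residue set
#'
#' The five residues (A, V, I, L, M) whose pair interactions carry
#' temperature dependence.
#'
#' @return character vector of one-letter codes.
#' @export
hydrophobicResidues <- function() .hydrophobicSet
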