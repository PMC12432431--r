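#' @include engine.R
NULL

# LAMMPS export uses the engine's "real" unit convention: Angstrom,
# kcal/mol, fs. All conversions from the internal nm/ps units happen here.
.nm2A <- 10

#' Write a LAMMPS data file for a system
#'
#' Emits an atom_style `full` molecular data file (atoms with molecule id,
#' type, charge and coordinates in Angstrom, plus harmonic bonds and
#' per-type masses).
#'
#' @param system a [SimSystem-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLammpsData <- function(system, path) {
  n <- beadCount(system)
  bonds <- .chainBondArrays(system)
  bv <- .beadVectors(system)
  nb <- length(bonds$i)
  bondKey <- paste(bonds$k, bonds$r0)
  bondTypes <- match(bondKey, unique(bondKey))
  nt <- nrow(system@typeTable)
  lines <- c(
    "LAMMPS data file: coarse-grained bead-spring chains (units real)",
    "",
    sprintf("%d atoms", n),
    sprintf("%d bonds", nb),
    sprintf("%d atom types", nt),
    sprintf("%d bond types", if (nb) max(bondTypes) else 0L),
    "",
    sprintf("0.0 %.10f xlo xhi", system@box[1] * .nm2A),
    sprintf("0.0 %.10f ylo yhi", system@box[2] * .nm2A),
    sprintf("0.0 %.10f zlo zhi", system@box[3] * .nm2A),
    "",
    "Masses",
    "",
    sprintf("%d %.6f  # %s", seq_len(nt), system@typeTable$mass,
            system@typeTable$code),
    "",
    "Atoms  # full",
    "")
  xyz <- system@coordinates * .nm2A
  lines <- c(lines, sprintf("%d %d %d %.6f %.10f %.10f %.10f",
                            seq_len(n), system@chainIndex, system@types,
                            bv$charge, xyz[, 1], xyz[, 2], xyz[, 3]))
  if (nb) {
    lines <- c(lines, "", "Bonds", "",
               sprintf("%d %d %d %d", seq_len(nb), bondTypes, bonds$i,
                       bonds$j))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a LAMMPS data file written by [writeLammpsData()]
#'
#' @param path data file path.
#' @return list with `coordinates` (nm), `box` (nm), `types`, `molecule`,
#'   `charge`, `masses` (per type), `bonds` (data.frame id, type, i, j).
#' @export
readLammpsData <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  getCount <- function(tag) {
    ln <- grep(paste0("^\\s*\\d+\\s+", tag, "\\s*$"), lines, value = TRUE)
    if (!length(ln)) stop("malformed data file: missing '", tag,
                          "' count", call. = FALSE)
    as.integer(sub("^\\s*(\\d+).*", "\\1", ln[1]))
  }
  n <- getCount("atoms"); nb <- getCount("bonds")
  nt <- getCount("atom types")
  boxLine <- function(tag) {
    ln <- grep(paste0(tag, "$"), lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  box <- c(boxLine("xlo xhi"), boxLine("ylo yhi"), boxLine("zlo zhi")) / .nm2A
  section <- function(name, count) {
    i <- grep(paste0("^", name, "\\b"), lines)
    if (!length(i)) stop("malformed data file: missing section ", name,
                         call. = FALSE)
    body <- lines[(i[1] + 2):(i[1] + 1 + count)]
    do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), function(x)
      suppressWarnings(as.numeric(x))))
  }
  mrows <- section("Masses", nt)
  arows <- section("Atoms", n)
  out <- list(
    coordinates = arows[, 5:7, drop = FALSE] / .nm2A,
    box = box,
    molecule = as.integer(arows[, 2]),
    types = as.integer(arows[, 3]),
    charge = arows[, 4],
    masses = mrows[, 2])
  out$bonds <- if (nb) {
    b <- section("Bonds", nb)
    data.frame(id = as.integer(b[, 1]), type = as.integer(b[, 2]),
               i = as.integer(b[, 3]), j = as.integer(b[, 4]))
  } else data.frame(id = integer(0), type = integer(0), i = integer(0),
                    j = integer(0))
  out
}

#' Write a tabulated pair potential in LAMMPS `pair_style table` format
#'
#' Samples the appropriate Wang-Frenkel branch on `n` points spanning
#' (0.01 nm, cutoff] and writes distance/energy/force triplets in real units
#' (Angstrom, kcal/mol, kcal/mol/Angstrom). Linear interpolation error
#' against the analytic potential is verified at write time.
#'
#' @param spec a [PairPotentialSpec-class].
#' @param path output file path.
#' @param keyword LAMMPS section keyword (default "PAIR").
#' @param n number of table nodes (default 2000).
#' @param tol maximum tolerated mid-node interpolation error, kcal/mol.
#' @return `path`, invisibly.
#' @export
writeLammpsPairTable <- function(spec, path, keyword = "PAIR", n = 2000L,
                                 tol = 1e-4) {
  cutoff <- if (spec@eps >= 0) spec@R else spec@rstar
  r <- seq(0.01, cutoff, length.out = n)
  tab <- pairTable(spec, r)
  # verify interpolation accuracy over the region the dynamics samples
  # (r >= sigma: well and tail); the sub-sigma core is intrinsically stiff
  # and only its order of magnitude matters there
  mid <- (r[-1] + r[-n]) / 2
  interp <- (tab$energy[-1] + tab$energy[-n]) / 2
  err <- max(abs(interp - pairPotential(mid, spec))[mid >= spec@sigma])
  if (err > tol)
    warning(sprintf(
      "pair table interpolation error %.2g kcal/mol exceeds %.2g; increase n",
      err, tol))
  lines <- c(
    sprintf("# Wang-Frenkel pair table: eps=%.8g kcal/mol sigma=%.8g nm",
            spec@eps, spec@sigma),
    "", keyword, sprintf("N %d", n), "",
    sprintf("%d %.16g %.16g %.16g", seq_len(n), r * .nm2A, tab$energy,
            tab$force / .nm2A))
  writeLines(lines, path)
  invisible(path)
}

#' Read a LAMMPS pair table written by [writeLammpsPairTable()]
#'
#' @param path table file path.
#' @return data.frame(r, energy, force) in nm, kcal/mol, kcal/mol/nm.
#' @export
readLammpsPairTable <- function(path) {
  lines <- readLines(path)
  nLine <- grep("^N \\d+", lines, value = TRUE)
  if (!length(nLine)) stop("malformed pair table: missing N line",
                           call. = FALSE)
  n <- as.integer(sub("^N (\\d+).*", "\\1", nLine[1]))
  body <- grep("^\\d+ ", lines, value = TRUE)
  if (length(body) != n) stop("malformed pair table: expected ", n,
                              " rows, found ", length(body), call. = FALSE)
  m <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  data.frame(r = m[, 2] / .nm2A, energy = m[, 3], force = m[, 4] * .nm2A)
}

#' Write a LAMMPS input script for a slab production run
#'
#' Encodes the production protocol: real units, tabulated pair styles, a
#' Langevin thermostat (default relaxation 5 ps) and a 50 ns equilibration
#' followed by a 400 ns production run at a 10 fs timestep, with z-density
#' chunk profiles written every 1 ns.
#'
#' @param system a [SimSystem-class].
#' @param path output file path.
#' @param dataFile name of the data file referenced by the script.
#' @param tableFiles named character vector of pair-table files, names
#'   "i:j" with 1-based type indices.
#' @param protocol list overriding `dtFs` (10), `dampPs` (5), `equilSteps`
#'   (5e6), `prodSteps` (4e7), `profileEverySteps` (1e5), `binWidthNm` (1).
#' @return `path`, invisibly.
#' @export
writeLammpsInput <- function(system, path, dataFile = "system.data",
                             tableFiles = character(), protocol = list()) {
  p <- modifyList(list(dtFs = 10, dampPs = 5, equilSteps = 5e6,
                       prodSteps = 4e7, profileEverySteps = 1e5,
                       binWidthNm = 1), protocol)
  bonds <- .chainBondArrays(system)
  kA <- unique(bonds$k)[1] / 100     # kcal/mol/nm^2 -> kcal/mol/A^2
  r0A <- unique(bonds$r0)[1] * .nm2A
  maxCut <- max(system@pair$cutoff, system@electro$cutoff) * .nm2A
  pairLines <- character(0)
  for (nm in names(tableFiles)) {
    ij <- as.integer(strsplit(nm, ":")[[1]])
    pairLines <- c(pairLines, sprintf("pair_coeff %d %d table %s PAIR",
                                      ij[1], ij[2], tableFiles[[nm]]))
  }
  lines <- c(
    "# slab production run (coarse-grained implicit-solvent model)",
    "units real", "dimension 3", "boundary p p p", "atom_style full",
    sprintf("read_data %s", dataFile),
    sprintf("pair_style table linear 2000 %.4f", maxCut),
    pairLines,
    "bond_style harmonic",
    sprintf("bond_coeff 1 %.6f %.6f", kA, r0A),
    "special_bonds lj/coul 0.0 1.0 1.0",
    "neighbor 3.0 bin", "neigh_modify every 1 delay 0 check yes",
    sprintf("timestep %.1f", p$dtFs),
    sprintf("velocity all create %.2f 4928459 dist gaussian",
            system@temperature),
    "fix integ all nve",
    sprintf("fix thermostat all langevin %.2f %.2f %.1f 325439",
            system@temperature, system@temperature, p$dampPs * 1000),
    "thermo 10000",
    sprintf("run %d  # equilibration", as.integer(p$equilSteps)),
    sprintf("compute zbins all chunk/atom bin/1d z lower %.2f units box",
            p$binWidthNm * .nm2A),
    sprintf(
      "fix zprof all ave/chunk %d 1 %d zbins density/mass file profile.dat",
      as.integer(p$profileEverySteps), as.integer(p$profileEverySteps)),
    sprintf("run %d  # production", as.integer(p$prodSteps)))
  writeLines(lines, path)
  invisible(path)
}

#' Export a complete LAMMPS input deck for a system
#'
#' Writes the data file, one tabulated pair potential per distinct residue
#' type pair at the system temperature, and the run-control input script.
#'
#' @param system a [SimSystem-class].
#' @param dir output directory (created if needed).
#' @param protocol protocol overrides, see [writeLammpsInput()].
#' @return list with elements `dataFile`, `pairTables` (named character
#'   vector), `inputScript`.
#' @export
writeLammpsExport <- function(system, dir, protocol = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dataFile <- file.path(dir, "system.data")
  writeLammpsData(system, dataFile)
  nt <- nrow(system@typeTable)
  tables <- character(0)
  for (a in seq_len(nt)) for (b in a:nt) {
    spec <- new("PairPotentialSpec", eps = system@pair$eps[a, b],
                sigma = system@pair$sigma[a, b], R = system@pair$R[a, b],
                mu = system@pair$mu[a, b], nu = system@pair$nu[a, b],
                alphaWF = system@pair$alpha[a, b],
                rstar = system@pair$rstar[a, b],
                repulsive = system@pair$eps[a, b] < 0)
    f <- file.path(dir, sprintf("pair_%s_%s.table",
                                system@typeTable$code[a],
                                system@typeTable$code[b]))
    writeLammpsPairTable(spec, f)
    tables[[paste(a, b, sep = ":")]] <- basename(f)
  }
  inputScript <- file.path(dir, "run.in")
  writeLammpsInput(system, inputScript, basename(dataFile), tables,
                   protocol)
  list(dataFile = dataFile,
       pairTables = vapply(names(tables), function(nm)
         file.path(dir, tables[[nm]]), character(1)),
       inputScript = inputScript)
}

#' Read a chunk-averaged z-density profile
#'
#' Parses the MD engine's text chunk-profile dialect (three comment header
#' lines, then per-frame blocks of `timestep nchunks total-count` followed by
#' `chunk coord ncount density` rows).
#'
#' @param path profile file path.
#' @param temperature temperature label for the profile, K.
#' @param dtFs timestep in fs used to convert timestep numbers to ns.
#' @param scale multiplier applied to the density column (use 1.66054 when
#'   the file stores amu/Angstrom^3 instead of g/cm^3).
#' @param coordUnit "A" (default) or "nm" for the coordinate column.
#' @return a [DensityProfile-class].
#' @export
readDensityProfile <- function(path, temperature = NA_real_, dtFs = 10,
                               scale = 1, coordUnit = c("A", "nm")) {
  coordUnit <- match.arg(coordUnit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  i <- 1L
  frames <- list(); steps <- numeric(0); coords <- NULL
  frameNo <- 0L
  while (i <= length(lines)) {
    hdr <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
    frameNo <- frameNo + 1L
    if (length(hdr) < 2 || any(is.na(hdr[1:2])))
      stop("malformed frame header at frame ", frameNo, call. = FALSE)
    nchunk <- as.integer(hdr[2])
    if (i + nchunk > length(lines))
      stop("truncated profile file in frame ", frameNo, call. = FALSE)
    block <- do.call(rbind, lapply(strsplit(trimws(
      lines[(i + 1):(i + nchunk)]), "\\s+"), as.numeric))
    if (any(is.na(block)))
      stop("malformed chunk rows in frame ", frameNo, call. = FALSE)
    cc <- block[, 2]
    if (is.null(coords)) coords <- cc
    else if (length(cc) != length(coords))
      stop("inconsistent bin count in frame ", frameNo, call. = FALSE)
    dens <- block[, ncol(block)] * scale
    frames[[frameNo]] <- dens
    steps <- c(steps, hdr[1])
    i <- i + 1L + nchunk
  }
  if (!length(frames)) stop("no frames found in ", path, call. = FALSE)
  if (coordUnit == "A") coords <- coords / .nm2A
  new("DensityProfile",
      temperature = as.numeric(temperature),
      binCenters = coords,
      densities = do.call(rbind, frames),
      frameTimes = steps * dtFs * 1e-6)
}

#' Write a density profile in the chunk-averaged text dialect
#'
#' Inverse of [readDensityProfile()]; used to build fixtures and to archive
#' internally computed profiles in the engine-compatible format.
#'
#' @param profile a [DensityProfile-class].
#' @param path output file path.
#' @param dtFs timestep used to convert frame times back to step numbers.
#' @return `path`, invisibly.
#' @export
writeDensityProfile <- function(profile, path, dtFs = 10) {
  lines <- c("# Chunk-averaged data", "# Timestep Number-of-chunks",
             "# Chunk Coord1 density/mass (g/cm^3, coord in Angstrom)")
  nb <- length(profile@binCenters)
  for (f in seq_len(nrow(profile@densities))) {
    step <- round(profile@frameTimes[f] / (dtFs * 1e-6))
    lines <- c(lines, sprintf("%d %d", step, nb),
               sprintf("%d %.6f %.10g", seq_len(nb),
                       profile@binCenters * .nm2A,
                       profile@densities[f, ]))
  }
  writeLines(lines, path)
  invisible(path)
}
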