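#' @include params.R
NULL

.checkSequence <- function(seq) {
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1]]
  bad <- which(!ch %in% .aaCodes)
  if (length(bad))
    stop(sprintf("illegal residue symbol '%s' at position %d", ch[bad[1]],
                 bad[1]), call. = FALSE)
  seq
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the 20 canonical one-letter
#' amino-acid codes; any other symbol is an error reporting the offending
#' symbol and its position.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are the FASTA
#'   identifiers, first whitespace-delimited token).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">elp", "VPGVGVPGVG"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  for (i in seq_along(seqs)) seqs[i] <- .checkSequence(seqs[i])
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  x <- Biostrings::AAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Build a bead-spring chain from a residue sequence
#'
#' Maps each residue to one coarse-grained bead carrying the mass, charge,
#' diameter, hydrophobic flag and homotypic well depth from the parameter
#' table, and joins consecutive beads with harmonic bonds.
#'
#' @param sequence one-letter residue string.
#' @param params model parameter list ([defaultModelParams()] /
#'   [loadModelParams()]).
#' @return a [ChainTopology-class].
#' @examples
#' ch <- buildChain("VPGVG", defaultModelParams(1))
#' beadCount(ch)  # 5
#' bondCount(ch)  # 4
#' @export
buildChain <- function(sequence, params = defaultModelParams()) {
  sequence <- .checkSequence(sequence)
  ch <- strsplit(sequence, "")[[1]]
  missing <- setdiff(unique(ch), params$residues$code)
  if (length(missing))
    stop("residue(s) missing from parameter table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  beads <- params$residues[ch, c("code", "mass", "charge", "sigma",
                                 "hydrophobic", "eps")]
  rownames(beads) <- NULL
  n <- length(ch)
  bonds <- if (n > 1L)
    data.frame(i = seq_len(n - 1L), j = seq_len(n - 1L) + 1L,
               k = params$bond$k, r0 = params$bond$r0)
  else data.frame(i = integer(0), j = integer(0), k = numeric(0),
                  r0 = numeric(0))
  new("ChainTopology", sequence = sequence, beads = beads, bonds = bonds)
}

#' Net charge of a chain
#'
#' @param chain a [ChainTopology-class].
#' @return numeric net charge in elementary-charge units.
#' @export
netCharge <- function(chain) {
  stopifnot(is(chain, "ChainTopology"))
  sum(chain@beads$charge)
}
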