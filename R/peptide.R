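# Monoisotopic residue masses (amu) for the 20 canonical amino acids, and
# the small-molecule constants used in fragment arithmetic.

#' Monoisotopic masses of the canonical amino-acid residues
#'
#' Named numeric vector of residue (not free amino acid) monoisotopic masses
#' in amu, one-letter codes. I and L are isobaric.
#'
#' @export
RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' Monoisotopic masses of small species used in fragment arithmetic (amu)
#'
#' `proton` (charge carrier), `H2O` (water, nominal 18), `NH3` (ammonia,
#' nominal 17) and `CO` (carbonyl, nominal 28; the b-to-a offset).
#'
#' @export
MASS_CONST <- c(proton = 1.00728, H2O = 18.01056, NH3 = 17.02655,
                CO = 27.99491)

#' Construct a Peptide
#'
#' Validates a one-letter amino-acid string against the canonical residue
#' table.
#'
#' @param sequence character scalar of one-letter residue codes.
#' @return An object of class `Peptide`: the uppercased sequence string with
#'   a `residues` attribute (character vector of codes).
#' @examples
#' p <- peptide("SAMPLER")
#' peptide_mass(p)
#' @export
peptide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L) {
    stop("sequence must be a non-empty character scalar", call. = FALSE)
  }
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!res %in% names(RESIDUE_MASSES))
  if (length(bad) > 0) {
    stop(sprintf("unknown residue '%s' at position %d", res[bad[1]], bad[1]),
         call. = FALSE)
  }
  structure(paste(res, collapse = ""), residues = res, class = "Peptide")
}

as_peptide <- function(x) {
  if (inherits(x, "Peptide")) x else peptide(x)
}

#' Residue codes of a Peptide
#' @param x a `Peptide` (or string coercible to one).
#' @return character vector of one-letter codes.
#' @export
residues <- function(x) attr(as_peptide(x), "residues")

#' Monoisotopic mass of a peptide (residue sum + water), amu
#' @param x a `Peptide` or sequence string.
#' @return numeric scalar.
#' @export
peptide_mass <- function(x) {
  sum(RESIDUE_MASSES[residues(x)]) + MASS_CONST[["H2O"]]
}

#' Cumulative prefix masses of a peptide
#'
#' The running sum of residue monoisotopic masses after each residue,
#' counting from the N-terminus. These are the "mass positions" used by
#' [match_score()] to decide whether two residues occupy the same place in
#' a peptide.
#'
#' @param x a `Peptide` or sequence string.
#' @return numeric vector of length `nchar(x)`, strictly increasing.
#' @examples
#' prefix_masses("GG")   # 57.02146 114.04293 (to rounding)
#' @export
prefix_masses <- function(x) {
  r <- residues(x)
  if (length(r) == 0) stop("empty peptide", call. = FALSE)
  unname(cumsum(RESIDUE_MASSES[r]))
}

#' @export
print.Peptide <- function(x, ...) {
  cat(sprintf("Peptide %s (%d residues, M = %.5f amu)\n",
              unclass(x), length(residues(x)), peptide_mass(x)))
  invisible(x)
}
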