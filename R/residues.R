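#' Amino-acid residue compositions
#'
#' Monoisotopic residue compositions (free amino acid minus water) for the
#' 20 canonical residues, as Hill-notation strings. A linear peptide is the
#' sum of its residues plus one water.
#'
#' @format Named character vector keyed by one-letter code.
#' @export
residue_formulas <- c(
  A = "C3H5NO",    R = "C6H12N4O",  N = "C4H6N2O2", D = "C4H5NO3",
  C = "C3H5NOS",   E = "C5H7NO3",   Q = "C5H8N2O2", G = "C2H3NO",
  H = "C6H7N3O",   I = "C6H11NO",   L = "C6H11NO",  K = "C6H12N2O",
  M = "C5H9NOS",   F = "C9H9NO",    P = "C5H7NO",   S = "C3H5NO2",
  T = "C4H7NO2",   W = "C11H10N2O", Y = "C9H9NO2",  V = "C5H9NO"
)

# Parsed residue formulas, memoised at load time.
residue_formula <- function(code) {
  bad <- setdiff(code, names(residue_formulas))
  if (length(bad) > 0) {
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  the$residues[code]
}

the <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  the$residues <- lapply(residue_formulas, parse_formula)
  the$water <- parse_formula("H2O")
}

water_formula <- function() the$water

#' Linear (unmodified) peptide formula
#'
#' Sum of residue compositions plus one water; free N-terminal amine and
#' C-terminal acid are assumed.
#'
#' @param sequence One-letter amino-acid string (or character vector of
#'   residues).
#' @return An [ms_formula].
#' @examples
#' linear_peptide_formula("GG")
#' @export
linear_peptide_formula <- function(sequence) {
  res <- split_sequence(sequence)
  res <- res[nzchar(res)]
  if (length(res) == 0) stop("empty peptide sequence", call. = FALSE)
  Reduce(`+`, residue_formula(res), water_formula())
}

split_sequence <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence[1]) > 1) {
    strsplit(sequence, "")[[1]]
  } else {
    as.character(sequence)
  }
}
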