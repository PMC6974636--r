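#' Monoisotopic atomic masses
#'
#' Monoisotopic masses (Da) of the elements handled by the formula algebra,
#' plus the proton mass used for charging. Values follow the IUPAC/CODATA
#' recommendations; carbon-12 is exactly 12 by definition. All mass
#' arithmetic in the package resolves element symbols against this table, so
#' supporting a further element is a one-line extension here.
#'
#' @format Named numeric vector of monoisotopic masses in daltons.
#' @export
atomic_masses <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

#' Proton mass in daltons
#'
#' Mass of the proton (not the hydrogen atom: the electron mass matters at
#' the fourth decimal of a doubly charged ion). Used by [ion_mz()] for
#' protonated adducts.
#'
#' @export
proton_mass <- 1.007276466621
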