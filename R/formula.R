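#' Elemental formulas
#'
#' An elemental formula is a named integer vector of non-negative element
#' counts carrying class `ms_formula`. Formulas print in Hill order (C, H,
#' then the remaining elements alphabetically) and zero counts are dropped,
#' so the printed string round-trips through [parse_formula()].
#'
#' @param counts Named integer-ish vector of element counts (e.g.
#'   `c(C = 76, H = 108)`). Names must appear in [atomic_masses].
#' @return An `ms_formula` object.
#' @examples
#' ms_formula(c(H = 2, O = 1))
#' parse_formula("C76H108N20O25S3")
#' @export
ms_formula <- function(counts = integer()) {
  if (length(counts) == 0) {
    return(structure(integer(), names = character(), class = "ms_formula"))
  }
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("element counts must be named", call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(atomic_masses))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("element counts must be non-negative", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("element counts must be whole numbers", call. = FALSE)
  }
  counts <- tapply(as.integer(round(counts)), names(counts), sum)
  counts <- counts[counts > 0]
  ord <- hill_order(names(counts))
  structure(as.integer(counts)[ord], names = names(counts)[ord],
            class = "ms_formula")
}

# Hill convention: C first, H second, everything else alphabetical.
hill_order <- function(elements) {
  rest <- sort(setdiff(elements, c("C", "H")))
  ordered <- c(intersect(c("C", "H"), elements), rest)
  match(ordered, elements)
}

#' Parse a Hill-notation formula string
#'
#' Accepts strings such as `"C76H108N20O25S3"` or `"CH4"`; an omitted count
#' means 1. Element symbols are one upper-case letter optionally followed by
#' one lower-case letter; anything else (including lower-case symbols such
#' as `"h4"`) is a parse error. Isotope labels and charge annotations are
#' not part of the grammar.
#'
#' @param text A single formula string.
#' @return An [ms_formula] object.
#' @examples
#' parse_formula("C76H108N20O25S3")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop("`text` must be a single string", call. = FALSE)
  }
  if (!nzchar(text)) stop("empty formula string", call. = FALSE)
  matches <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, list(matches))[[1]]
  if (sum(attr(matches, "match.length")) != nchar(text)) {
    stop("malformed formula string: ", text, call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", tokens)
  n <- sub("^[A-Za-z]+", "", tokens)
  n <- ifelse(nzchar(n), suppressWarnings(as.integer(n)), 1L)
  ms_formula(stats::setNames(n, sym))
}

#' Render a formula in canonical Hill notation
#'
#' @param f An [ms_formula].
#' @return A single string; `render_formula(parse_formula(x))` is canonical.
#' @export
render_formula <- function(f) {
  f <- unclass(as_ms_formula(f))
  if (length(f) == 0) return("")
  paste0(names(f), ifelse(f == 1L, "", as.character(f)), collapse = "")
}

as_ms_formula <- function(x) {
  if (inherits(x, "ms_formula")) return(x)
  if (is.character(x) && length(x) == 1) return(parse_formula(x))
  if (is.numeric(x)) return(ms_formula(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an elemental formula", call. = FALSE)
}

#' @export
format.ms_formula <- function(x, ...) render_formula(x)

#' @export
print.ms_formula <- function(x, ...) {
  cat("<formula> ", render_formula(x), "  (",
      format(monoisotopic_mass(x), nsmall = 4), " Da)\n", sep = "")
  invisible(x)
}

#' @export
`+.ms_formula` <- function(e1, e2) {
  e1 <- as_ms_formula(e1); e2 <- as_ms_formula(e2)
  all_el <- union(names(e1), names(e2))
  out <- stats::setNames(integer(length(all_el)), all_el)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] + unclass(e2)
  ms_formula(out)
}

#' @export
`-.ms_formula` <- function(e1, e2) {
  if (missing(e2)) stop("unary minus is not defined for formulas", call. = FALSE)
  e1 <- as_ms_formula(e1); e2 <- as_ms_formula(e2)
  all_el <- union(names(e1), names(e2))
  out <- stats::setNames(integer(length(all_el)), all_el)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] - unclass(e2)
  if (any(out < 0)) {
    neg <- names(out)[out < 0]
    stop("subtraction yields negative count for: ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  ms_formula(out)
}

#' @export
`*.ms_formula` <- function(e1, e2) {
  if (inherits(e1, "ms_formula")) { f <- e1; k <- e2 } else { f <- e2; k <- e1 }
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k != round(k)) {
    stop("a formula can only be multiplied by a single non-negative integer",
         call. = FALSE)
  }
  ms_formula(stats::setNames(as.integer(f) * as.integer(k), names(f)))
}

#' @export
`==.ms_formula` <- function(e1, e2) {
  identical(render_formula(as_ms_formula(e1)), render_formula(as_ms_formula(e2)))
}

#' Monoisotopic mass of a formula
#'
#' Sum of element count times monoisotopic atomic mass over [atomic_masses].
#' Additive: `monoisotopic_mass(a + b)` equals
#' `monoisotopic_mass(a) + monoisotopic_mass(b)`.
#'
#' @param f An [ms_formula], or a formula string.
#' @return Mass in daltons (full precision; see [format_mz()] for report
#'   rounding).
#' @examples
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(f) {
  f <- as_ms_formula(f)
  if (length(f) == 0) return(0)
  sum(atomic_masses[names(f)] * as.numeric(f))
}

#' m/z of a protonated ion
#'
#' m/z of the `[M + zH]^z+` ion: `(M + z * proton_mass) / z` with `M` the
#' monoisotopic mass of `f`. Protonation uses the proton mass, not the
#' hydrogen-atom mass. Values are returned at full precision; reporting
#' surfaces round half-even to 4 decimal places via [format_mz()].
#'
#' @param f Formula (object or string).
#' @param z Positive integer charge.
#' @return m/z in daltons per unit charge.
#' @examples
#' ion_mz("C76H108N20O25S3", 2)
#' @export
ion_mz <- function(f, z) {
  if (!is.numeric(z) || length(z) != 1 || is.na(z) || z < 1 || z != round(z)) {
    stop("`z` must be a positive integer charge", call. = FALSE)
  }
  (monoisotopic_mass(f) + z * proton_mass) / z
}

#' Signed parts-per-million mass error
#'
#' `(observed - calculated) / calculated * 1e6`, the accuracy metric used to
#' assign identity to an observed ion. Vectorised over both arguments.
#'
#' @param observed,calculated Observed and calculated m/z; `calculated` must
#'   be positive.
#' @return Signed ppm error (full precision; see [format_ppm()]).
#' @examples
#' ppm_error(899.3553, 899.3551)
#' @export
ppm_error <- function(observed, calculated) {
  if (any(!is.finite(calculated)) || any(calculated <= 0)) {
    stop("`calculated` m/z must be positive", call. = FALSE)
  }
  (observed - calculated) / calculated * 1e6
}

#' Report rounding helpers
#'
#' m/z values are reported to 4 decimal places and ppm errors to 2, both
#' rounded half-even (the behaviour of base [round()]); full precision is
#' kept internally everywhere.
#'
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @export
format_mz <- function(x) round(x, 4)

#' @rdname format_mz
#' @export
format_ppm <- function(x) round(x, 2)
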