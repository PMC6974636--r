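#' Elemental formula of the mature (fully modified) peptide
#'
#' Starting from the linear peptide, each dehydration removes one water and
#' each beta-hydroxylation adds one oxygen. Thioether cyclisation and
#' lysinoalanine formation are Michael additions across the dehydrated
#' residue and change no atoms, so the bridge topology affects
#' fragmentation but not the intact mass.
#'
#' @param s A [lanthipeptide] structure.
#' @param hydroxylated If `FALSE`, derive the "deoxy" species lacking the
#'   Asp hydroxyl oxygen(s).
#' @return An [ms_formula].
#' @examples
#' mature_formula(kyamicin_structure())
#' mature_formula(kyamicin_structure(), hydroxylated = FALSE)
#' @export
mature_formula <- function(s, hydroxylated = TRUE) {
  stopifnot(inherits(s, "lanthipeptide"))
  f <- linear_peptide_formula(s$core_sequence) -
    length(s$dehydrations) * water_formula()
  if (isTRUE(hydroxylated) && length(s$hydroxylations) > 0) {
    f <- f + length(s$hydroxylations) * ms_formula(c(O = 1))
  }
  f
}

#' Formula after chemical desulfurisation of k thioether bridges
#'
#' NiCl2/NaBH4 reduction cleaves each (methyl)lanthionine bridge with the
#' loss of its sulfur atom and the gain of two hydrogens; the lysinoalanine
#' bridge is untouched. `k = 0` is the mature species.
#'
#' @inheritParams mature_formula
#' @param k Number of bridges reduced, `0..n_bridges`.
#' @return An [ms_formula].
#' @examples
#' reduced_formula(kyamicin_structure(), 3)
#' @export
reduced_formula <- function(s, k, hydroxylated = TRUE) {
  stopifnot(inherits(s, "lanthipeptide"))
  nb <- n_bridges(s)
  if (!is.numeric(k) || length(k) != 1 || k < 0 || k > nb ||
      k != round(k)) {
    stop("`k` must be an integer in 0..", nb, call. = FALSE)
  }
  k <- as.integer(k)
  f <- mature_formula(s, hydroxylated = hydroxylated)
  if (k > 0) {
    f <- f + k * ms_formula(c(H = 2)) - k * ms_formula(c(S = 1))
  }
  f
}

#' Declare a concrete chemical species of a structure
#'
#' A species variant pins down the optional modification states of a
#' structure: whether the Asp hydroxylation is present (`FALSE` gives the
#' "deoxy" species) and how many thioether bridges have been chemically
#' reduced.
#'
#' @inheritParams mature_formula
#' @param reduced_bridges Integer `k` in `0..n_bridges`.
#' @param label Species label; a default is derived from the structure
#'   name and the modification state.
#' @return A `species_variant` object.
#' @examples
#' species_variant(kyamicin_structure(), hydroxylated = FALSE)
#' @export
species_variant <- function(s, hydroxylated = TRUE, reduced_bridges = 0,
                            label = NULL) {
  f <- reduced_formula(s, reduced_bridges, hydroxylated = hydroxylated)
  if (is.null(label)) {
    label <- paste0(if (!hydroxylated) "deoxy", s$name)
    if (reduced_bridges > 0) {
      label <- paste0(label, " (-", reduced_bridges, "S)")
    }
  }
  structure(
    list(structure = s, hydroxylated = isTRUE(hydroxylated),
         reduced_bridges = as.integer(reduced_bridges),
         label = label, formula = f),
    class = "species_variant"
  )
}

#' @export
print.species_variant <- function(x, ...) {
  cat("<species> ", x$label, ": ", render_formula(x$formula), "  M = ",
      format(monoisotopic_mass(x$formula), nsmall = 4), " Da\n", sep = "")
  invisible(x)
}

#' Predicted ion table for a set of species
#'
#' Computes protonated-ion m/z for every (variant, charge) combination —
#' the prediction side of an extracted-ion screening workflow.
#'
#' @param variants A `species_variant`, a `lanthipeptide` (taken as its
#'   mature variant), or a list of either.
#' @param charges Integer vector of positive charges.
#' @return A tibble with columns `species`, `hydroxylated`,
#'   `reduced_bridges`, `formula`, `charge`, `mz`.
#' @examples
#' predict_ions(kyamicin_structure(), charges = 2)
#' @export
predict_ions <- function(variants, charges = 2) {
  variants <- as_variant_list(variants)
  if (length(variants) == 0) stop("no species supplied", call. = FALSE)
  if (length(charges) == 0 || any(charges < 1)) {
    stop("`charges` must be positive integers", call. = FALSE)
  }
  rows <- purrr::map(variants, function(v) {
    tibble::tibble(
      species = v$label,
      hydroxylated = v$hydroxylated,
      reduced_bridges = v$reduced_bridges,
      formula = render_formula(v$formula),
      charge = as.integer(sort(unique(charges))),
      mz = vapply(as.integer(sort(unique(charges))),
                  function(z) ion_mz(v$formula, z), numeric(1))
    )
  })
  dplyr::bind_rows(rows)
}

as_variant_list <- function(variants) {
  if (inherits(variants, "species_variant")) return(list(variants))
  if (inherits(variants, "lanthipeptide")) {
    return(list(species_variant(variants)))
  }
  if (is.list(variants)) {
    return(purrr::map(variants, function(v) {
      if (inherits(v, "lanthipeptide")) species_variant(v)
      else if (inherits(v, "species_variant")) v
      else stop("`variants` must contain lanthipeptide structures or ",
                "species variants", call. = FALSE)
    }))
  }
  stop("`variants` must be a structure, a species variant, or a list of them",
       call. = FALSE)
}

#' Desulfurisation ladder of a structure
#'
#' Ions for `k = 0..n_bridges` reduced bridges at a fixed charge — the
#' species ladder observed while following a NiCl2/NaBH4 reduction by LC-MS.
#' At `z = 2`, consecutive ions are spaced by `(m_S - 2 m_H) / 2` (about
#' 14.9782).
#'
#' @inheritParams mature_formula
#' @param charge Positive integer charge (default 2, the dominant
#'   electrospray state for this family).
#' @return A tibble with columns `k`, `species`, `formula`, `charge`, `mz`,
#'   ordered by `k`.
#' @examples
#' reduction_series(kyamicin_structure())
#' @export
reduction_series <- function(s, charge = 2, hydroxylated = TRUE) {
  stopifnot(inherits(s, "lanthipeptide"))
  ks <- 0:n_bridges(s)
  variants <- purrr::map(ks, function(k) {
    species_variant(s, hydroxylated = hydroxylated, reduced_bridges = k)
  })
  out <- predict_ions(variants, charges = charge)
  tibble::tibble(
    k = ks,
    species = out$species,
    formula = out$formula,
    charge = out$charge,
    mz = out$mz
  )
}
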