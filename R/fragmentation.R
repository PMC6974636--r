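#' Residue substitutions at a severed lysinoalanine bridge
#'
#' In MALDI-TOF LIFT spectra of the desulfurised peptide, fragmentation at
#' the lysinoalanine bridge proceeds via a rearrangement: the Dha-derived
#' donor is read as a glycine residue and the Lys acceptor retains the
#' bridge carbon as an N=CH2 methylene imine on its side-chain amine
#' (net +CH2, -2H relative to lysine). The two substituted residues
#' together carry exactly the atoms of the intact cross-linked pair, so
#' complementary fragments always sum to the precursor composition.
#'
#' @param s A [lanthipeptide] with a lysinoalanine bridge.
#' @return Named list of [ms_formula] substitutions keyed by position.
#' @examples
#' rearranged_residues(kyamicin_structure())
#' @export
rearranged_residues <- function(s) {
  stopifnot(inherits(s, "lanthipeptide"))
  if (is.null(s$lysinoalanine)) {
    stop("structure has no lysinoalanine bridge", call. = FALSE)
  }
  la <- s$lysinoalanine
  # Lys + CH2 - 2H: the bridge methylene stays on the side-chain nitrogen
  # as N=CH2, so the substituted residue is lysine plus one carbon.
  subs <- list(
    residue_formula("G")[[1]],
    residue_formula("K")[[1]] + ms_formula(c(C = 1, H = 2)) -
      ms_formula(c(H = 2))
  )
  names(subs) <- as.character(la)
  subs
}

# Residue composition at each position of a (partially) reduced peptide.
# Bridges are reduced in list order; a reduced MeLan/Lan reverts its Cys
# member to Ala and its Dhb/Dha member to Abu/Ala, apportioning the
# whole-molecule -S +2H shift to the two members. Intact thioether members
# keep their bridged (mass-neutral) forms; the lysinoalanine donor stays a
# Dha. Hydroxylated Asp gains one oxygen.
reduced_residue_formulas <- function(s, k_reduced, hydroxylated = TRUE) {
  res <- split_sequence(s$core_sequence)
  forms <- residue_formula(res)
  reduced_pos <- unlist(s$thioether_bridges[seq_len(k_reduced)])
  o1 <- ms_formula(c(O = 1))
  for (i in seq_along(res)) {
    if (i %in% s$dehydrations) {
      forms[[i]] <- forms[[i]] - water_formula()  # Dha / Dhb
      if (i %in% reduced_pos) {
        forms[[i]] <- forms[[i]] + ms_formula(c(H = 2))  # back to Ala / Abu
      }
    } else if (res[i] == "C" && i %in% reduced_pos) {
      forms[[i]] <- forms[[i]] - ms_formula(c(S = 1))  # Cys -> Ala
    }
    if (isTRUE(hydroxylated) && i %in% s$hydroxylations) {
      forms[[i]] <- forms[[i]] + o1
    }
  }
  forms
}

#' y-ion ladder of the (reduced) peptide
#'
#' Generates the singly protonated y-ion series `y_1..y_{L-1}` (C-terminal
#' fragments plus water), the series read from MALDI-TOF LIFT spectra of
#' the desulfurised peptide. Fragment spans that sever the lysinoalanine
#' bridge apply the [rearranged_residues()] substitutions; spans containing
#' both bridge partners keep the intact, mass-neutral cross-link. Spans
#' that sever a still-intact thioether bridge are flagged — such fragments
#' are not expected in a spectrum unless the bridge is reduced.
#'
#' @param s A [lanthipeptide].
#' @param k_reduced Number of thioether bridges reduced (default: all, the
#'   state actually fragmented in the characterisation experiment).
#' @param hydroxylated Include the Asp hydroxyl oxygen(s).
#' @return A `fragment_ladder` tibble with columns `series`, `index`,
#'   `span_start`, `span_end`, `formula`, `mz` (z = 1), `rearranged`,
#'   `severs_thioether`.
#' @examples
#' y_ion_ladder(kyamicin_structure())
#' @export
y_ion_ladder <- function(s, k_reduced = n_bridges(s), hydroxylated = TRUE) {
  stopifnot(inherits(s, "lanthipeptide"))
  nb <- n_bridges(s)
  if (!is.numeric(k_reduced) || length(k_reduced) != 1 || k_reduced < 0 ||
      k_reduced > nb || k_reduced != round(k_reduced)) {
    stop("`k_reduced` must be an integer in 0..", nb, call. = FALSE)
  }
  k_reduced <- as.integer(k_reduced)
  len <- nchar(s$core_sequence)
  forms <- reduced_residue_formulas(s, k_reduced, hydroxylated)
  la <- s$lysinoalanine
  subs <- if (!is.null(la)) rearranged_residues(s)
  intact <- s$thioether_bridges[seq_len(nb) > k_reduced]

  rows <- purrr::map(seq_len(len - 1), function(n) {
    span <- (len - n + 1):len
    span_forms <- forms[span]
    rearranged <- FALSE
    if (!is.null(la)) {
      in_span <- la %in% span
      if (xor(in_span[1], in_span[2])) {
        cut_pos <- la[in_span]
        idx <- match(cut_pos, span)
        span_forms[[idx]] <- subs[[as.character(cut_pos)]]
        rearranged <- TRUE
      }
    }
    severs <- any(vapply(intact, function(p) xor(p[1] %in% span,
                                                 p[2] %in% span), logical(1)))
    f <- Reduce(`+`, span_forms, water_formula())
    tibble::tibble(
      series = "y", index = n,
      span_start = span[1], span_end = len,
      formula = render_formula(f),
      mz = ion_mz(f, 1),
      rearranged = rearranged,
      severs_thioether = severs
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("fragment_ladder", class(out)),
            peptide = s$name, k_reduced = k_reduced)
}

#' Match an observed peak list against a fragment ladder
#'
#' For each fragment the nearest observed peak (in ppm) is reported;
#' fragments with no peak inside `tol_ppm` are marked unmatched. A peak
#' claimed by more than one fragment within tolerance is flagged ambiguous
#' rather than silently double-assigned.
#'
#' @param peaks A peak list (see [as_peaklist()]) or a data frame with an
#'   `mz` column.
#' @param ladder A `fragment_ladder` from [y_ion_ladder()].
#' @param tol_ppm Match tolerance in ppm.
#' @return The ladder tibble with added columns `mz_obs`, `intensity`,
#'   `ppm`, `matched`, `ambiguous`.
#' @export
match_ladder <- function(peaks, ladder, tol_ppm = 10) {
  peaks <- as_peaklist(peaks)
  if (nrow(peaks) == 0) stop("empty peak list", call. = FALSE)
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) {
    stop("`tol_ppm` must be positive", call. = FALSE)
  }
  hit <- purrr::map(ladder$mz, function(m) nearest_peak(peaks, m))
  out <- ladder
  out$mz_obs <- vapply(hit, function(h) h$mz, numeric(1))
  out$intensity <- vapply(hit, function(h) h$intensity, numeric(1))
  out$ppm <- ppm_error(out$mz_obs, out$mz)
  out$matched <- abs(out$ppm) <= tol_ppm
  out$mz_obs[!out$matched] <- NA_real_
  out$intensity[!out$matched] <- NA_real_
  out$ppm[!out$matched] <- NA_real_
  out$ambiguous <- out$matched &
    out$mz_obs %in% out$mz_obs[out$matched][duplicated(out$mz_obs[out$matched])]
  out
}
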