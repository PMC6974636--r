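#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a match report
#'
#' Returns the per-ion annotation rows as a plain tibble, with report
#' rounding applied (`mz` to 4 decimals, `ppm` to 2).
#'
#' @param x A `match_report` from [screen_species()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy match_report
#' @export
tidy.match_report <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$mz <- format_mz(out$mz)
  out$mz_obs <- format_mz(out$mz_obs)
  out$ppm <- format_ppm(out$ppm)
  out
}

#' Summarise a match report
#'
#' @inheritParams tidy.match_report
#' @return One-row tibble: `n_queried`, `n_detected`, `max_abs_ppm`,
#'   `tol_ppm`.
#' @method glance match_report
#' @export
glance.match_report <- function(x, ...) {
  tibble::tibble(
    n_queried = nrow(x),
    n_detected = sum(x$detected),
    max_abs_ppm = if (any(x$detected)) max(abs(x$ppm), na.rm = TRUE) else
      NA_real_,
    tol_ppm = attr(x, "tol_ppm")
  )
}

#' Tidy a fragment ladder
#'
#' @param x A `fragment_ladder` from [y_ion_ladder()].
#' @param ... Unused.
#' @return A tibble with `mz` rounded to 4 decimals.
#' @method tidy fragment_ladder
#' @export
tidy.fragment_ladder <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$mz <- format_mz(out$mz)
  out
}

#' Summarise a fragment ladder
#'
#' @inheritParams tidy.fragment_ladder
#' @return One-row tibble: `peptide`, `k_reduced`, `n_ions`, `mz_min`,
#'   `mz_max`, `n_rearranged`.
#' @method glance fragment_ladder
#' @export
glance.fragment_ladder <- function(x, ...) {
  tibble::tibble(
    peptide = attr(x, "peptide"),
    k_reduced = attr(x, "k_reduced"),
    n_ions = nrow(x),
    mz_min = min(x$mz),
    mz_max = max(x$mz),
    n_rearranged = sum(x$rearranged)
  )
}
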