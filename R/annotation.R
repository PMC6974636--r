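#' Peak lists
#'
#' A peak list is a tibble of observed ions with columns `mz` (positive),
#' `intensity` (non-negative, default 1) and optionally `rt` (minutes).
#' Canonical form is sorted ascending by `mz`. Retention time is carried
#' through but never used for matching.
#'
#' @param x A data frame with an `mz` column.
#' @return A `peaklist` tibble sorted by `mz`.
#' @examples
#' as_peaklist(data.frame(mz = c(900.1, 899.4), intensity = c(2, 5)))
#' @export
as_peaklist <- function(x) {
  if (inherits(x, "peaklist")) return(x)
  if (!is.data.frame(x) || !"mz" %in% names(x)) {
    stop("a peak list needs an `mz` column", call. = FALSE)
  }
  out <- tibble::as_tibble(x)
  if (!is.numeric(out$mz)) stop("`mz` must be numeric", call. = FALSE)
  if (any(!is.finite(out$mz)) || any(out$mz <= 0)) {
    stop("`mz` values must be positive and finite", call. = FALSE)
  }
  if (!"intensity" %in% names(out)) out$intensity <- 1
  if (!is.numeric(out$intensity) || any(out$intensity < 0, na.rm = TRUE)) {
    stop("`intensity` must be non-negative numeric", call. = FALSE)
  }
  keep <- intersect(c("mz", "intensity", "rt"), names(out))
  out <- dplyr::arrange(out[keep], .data$mz)
  structure(out, class = c("peaklist", class(tibble::tibble())))
}

#' Read a peak list from CSV
#'
#' Expects a column `mz`; `intensity` (default 1) and `rt` are optional.
#'
#' @param path CSV file path.
#' @return A `peaklist` tibble.
#' @export
read_peaklist <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(df) == 0) stop("empty peak list file: ", path, call. = FALSE)
  as_peaklist(df)
}

#' Write a peak list or report to CSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}

# Nearest peak in ppm; ties broken by higher intensity, then lower mz.
nearest_peak <- function(peaks, mz_calc) {
  d <- abs(ppm_error(peaks$mz, mz_calc))
  best <- which(d == min(d))
  if (length(best) > 1) {
    best <- best[order(-peaks$intensity[best], peaks$mz[best])][1]
  }
  list(mz = peaks$mz[best], intensity = peaks$intensity[best],
       ppm = ppm_error(peaks$mz[best], mz_calc))
}

#' Screen a peak list for predicted species
#'
#' The in-silico analogue of extracted-ion screening: every queried
#' (species, charge) ion is annotated with its nearest observed peak and
#' the signed ppm error, and called detected when the error is within
#' tolerance. Every queried ion appears in the report, detected or not,
#' and the result is invariant to the input ordering of peaks and species.
#'
#' @param peaks A peak list (or data frame with `mz`).
#' @param variants Structures or species variants (see [predict_ions()]).
#' @param charges Integer charges to query (default 2).
#' @param tol_ppm Detection tolerance in ppm. The default 10 covers the
#'   mass accuracy of a lock-mass-corrected TOF instrument with margin.
#' @return A `match_report` tibble: the [predict_ions()] columns plus
#'   `mz_obs`, `intensity`, `ppm`, `detected`.
#' @examples
#' pk <- as_peaklist(data.frame(mz = 899.3553))
#' screen_species(pk, kyamicin_structure())
#' @export
screen_species <- function(peaks, variants, charges = 2, tol_ppm = 10) {
  peaks <- as_peaklist(peaks)
  if (!is.numeric(tol_ppm) || length(tol_ppm) != 1 || tol_ppm <= 0) {
    stop("`tol_ppm` must be a positive number", call. = FALSE)
  }
  ions <- predict_ions(variants, charges = charges)
  ions <- dplyr::arrange(ions, .data$species, .data$charge)
  if (nrow(peaks) == 0) stop("empty peak list", call. = FALSE)
  hit <- purrr::map(ions$mz, function(m) nearest_peak(peaks, m))
  out <- ions
  out$mz_obs <- vapply(hit, function(h) h$mz, numeric(1))
  out$intensity <- vapply(hit, function(h) h$intensity, numeric(1))
  out$ppm <- ppm_error(out$mz_obs, out$mz)
  out$detected <- abs(out$ppm) <= tol_ppm
  out$mz_obs[!out$detected] <- NA_real_
  out$intensity[!out$detected] <- NA_real_
  out$ppm[!out$detected] <- NA_real_
  structure(out, class = c("match_report", class(out)), tol_ppm = tol_ppm)
}
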