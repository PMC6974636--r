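#' Simulate a UPLC-MS peak list with known ground truth
#'
#' Emulates the statistical structure of an extracted-ion screening input:
#' each predicted ion appears at its calculated m/z perturbed by a Gaussian
#' ppm error, some true peaks may drop out, and uniform-random decoy peaks
#' are added. Decoys are kept out of a +/- 3 sigma ppm window around every
#' true ion so the ground truth is unambiguous. Intensities are log-normal.
#' All randomness derives from `seed`; the caller's RNG state is left
#' untouched, and the same seed reproduces the same list exactly.
#'
#' @param ions A tibble of predicted ions with columns `species` and `mz`
#'   (e.g. from [predict_ions()] or [reduction_series()]).
#' @param ppm_sigma Gaussian m/z error scale in ppm (default 2, the error
#'   scale of a calibrated high-resolution TOF; observed errors in the
#'   motivating study stay below 3.5 ppm).
#' @param n_decoys Number of decoy peaks.
#' @param mz_range Length-2 numeric range for decoys; defaults to the ion
#'   range widened by 5%.
#' @param dropout Per-ion probability that the true peak is omitted.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity
#'   parameters.
#' @param seed Integer seed.
#' @return A list with elements `peaks` (a `peaklist`) and `truth` (tibble
#'   with columns `kind`, `species`, `mz_true`, `mz`, `ppm`, `included`).
#' @examples
#' sim <- simulate_peaklist(reduction_series(kyamicin_structure()),
#'                          n_decoys = 20, seed = 1)
#' sim$peaks
#' @export
simulate_peaklist <- function(ions, ppm_sigma = 2, n_decoys = 0,
                              mz_range = NULL, dropout = 0,
                              intensity_meanlog = log(1e4),
                              intensity_sdlog = 1, seed = 1) {
  if (!is.data.frame(ions) || !"mz" %in% names(ions)) {
    stop("`ions` must be a data frame with an `mz` column", call. = FALSE)
  }
  if (nrow(ions) == 0 && n_decoys == 0) {
    stop("nothing to simulate: no ions and no decoys", call. = FALSE)
  }
  if (!is.numeric(ppm_sigma) || ppm_sigma < 0) {
    stop("`ppm_sigma` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(dropout) || dropout < 0 || dropout > 1) {
    stop("`dropout` must be in [0, 1]", call. = FALSE)
  }
  species <- if ("species" %in% names(ions)) ions$species else
    sprintf("ion_%d", seq_len(nrow(ions)))
  if (is.null(mz_range)) {
    span <- range(ions$mz)
    pad <- 0.05 * max(diff(span), 1)
    mz_range <- c(span[1] - pad, span[2] + pad)
  }

  with_preserved_rng(seed, {
    eps <- stats::rnorm(nrow(ions), 0, ppm_sigma)
    mz_true <- ions$mz
    mz_obs <- mz_true * (1 + eps / 1e6)
    included <- stats::runif(nrow(ions)) >= dropout
    true_int <- stats::rlnorm(nrow(ions), intensity_meanlog, intensity_sdlog)

    decoy_mz <- numeric(0)
    if (n_decoys > 0) {
      exclude_lo <- mz_true * (1 - 3 * ppm_sigma / 1e6)
      exclude_hi <- mz_true * (1 + 3 * ppm_sigma / 1e6)
      decoy_mz <- rejection_sample_uniform(n_decoys, mz_range,
                                           exclude_lo, exclude_hi)
    }
    decoy_int <- stats::rlnorm(length(decoy_mz), intensity_meanlog,
                               intensity_sdlog)

    truth <- dplyr::bind_rows(
      tibble::tibble(kind = "true", species = species, mz_true = mz_true,
                     mz = mz_obs, ppm = eps, included = included),
      tibble::tibble(kind = "decoy", species = NA_character_,
                     mz_true = NA_real_, mz = decoy_mz, ppm = NA_real_,
                     included = TRUE)
    )
    peaks <- as_peaklist(tibble::tibble(
      mz = c(mz_obs[included], decoy_mz),
      intensity = c(true_int[included], decoy_int)
    ))
    list(peaks = peaks, truth = truth)
  })
}

# Uniform draws on `range` avoiding the union of [lo_i, hi_i] windows.
rejection_sample_uniform <- function(n, range, lo, hi, max_tries = 10000) {
  out <- numeric(0)
  tries <- 0
  while (length(out) < n && tries < max_tries) {
    draw <- stats::runif(n - length(out), range[1], range[2])
    ok <- vapply(draw, function(x) !any(x >= lo & x <= hi), logical(1))
    out <- c(out, draw[ok])
    tries <- tries + 1
  }
  if (length(out) < n) {
    stop("could not place decoy peaks outside exclusion windows",
         call. = FALSE)
  }
  out
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Randomised valid structures for property testing
#'
#' Generates structures sharing the composition of `base` but with the
#' residues at unconstrained positions permuted — bridge members, the
#' lysinoalanine pair and hydroxylation sites stay fixed so every output
#' satisfies the structure invariants. Useful as fuel for conservation and
#' round-trip property tests.
#'
#' @param base A valid [lanthipeptide].
#' @param n Number of structures.
#' @param seed Integer seed.
#' @return List of `lanthipeptide` objects (empty when `n = 0`).
#' @export
simulate_variant_structures <- function(base, n, seed = 1) {
  stopifnot(inherits(base, "lanthipeptide"))
  if (n == 0) return(list())
  res <- split_sequence(base$core_sequence)
  fixed <- sort(unique(c(unlist(base$thioether_bridges), base$dehydrations,
                         base$lysinoalanine, base$hydroxylations)))
  free <- setdiff(seq_along(res), fixed)
  with_preserved_rng(seed, {
    purrr::map(seq_len(n), function(i) {
      res2 <- res
      res2[free] <- res[free[sample.int(length(free))]]
      lanthipeptide(
        name = paste0(base$name, "_perm", i),
        core_sequence = paste(res2, collapse = ""),
        dehydrations = base$dehydrations,
        thioether_bridges = base$thioether_bridges,
        lysinoalanine = base$lysinoalanine,
        hydroxylations = base$hydroxylations
      )
    })
  })
}
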