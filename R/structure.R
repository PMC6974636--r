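#' Declare a cross-linked lanthipeptide structure
#'
#' A `lanthipeptide` object records a core peptide together with its
#' post-translational modification topology, using 1-based residue
#' positions throughout:
#'
#' * `dehydrations` — Ser/Thr positions dehydrated to Dha/Dhb (one water
#'   lost each);
#' * `thioether_bridges` — unordered position pairs forming
#'   (methyl)lanthionine bridges; each pair has exactly one Cys member, the
#'   other member must be dehydrated, and no position sits in two bridges;
#' * `lysinoalanine` — optional (dehydrated-Ser position, Lys position)
#'   pair;
#' * `hydroxylations` — Asp positions carrying a beta-hydroxyl (one oxygen
#'   gained each).
#'
#' Cyclisation steps (thioether and lysinoalanine formation) are additions
#' across a double bond and change no atoms; all mass arithmetic therefore
#' reduces to counting dehydrations and hydroxylations, which is what
#' [mature_formula()] does.
#'
#' @param name Species label, e.g. `"kyamicin"`.
#' @param core_sequence One-letter core peptide string.
#' @param dehydrations Integer positions (must carry S or T).
#' @param thioether_bridges List of length-2 integer vectors.
#' @param lysinoalanine Length-2 integer vector `(Dha position, Lys
#'   position)`, or `NULL`.
#' @param hydroxylations Integer positions (must carry D).
#' @return A validated `lanthipeptide` object.
#' @examples
#' kyamicin_structure()
#' @export
lanthipeptide <- function(name, core_sequence, dehydrations = integer(),
                          thioether_bridges = list(), lysinoalanine = NULL,
                          hydroxylations = integer()) {
  s <- structure(
    list(
      name = as.character(name),
      core_sequence = toupper(as.character(core_sequence)),
      dehydrations = sort(as.integer(dehydrations)),
      thioether_bridges = lapply(thioether_bridges,
                                 function(p) sort(as.integer(p))),
      lysinoalanine = if (!is.null(lysinoalanine)) as.integer(lysinoalanine),
      hydroxylations = sort(as.integer(hydroxylations))
    ),
    class = "lanthipeptide"
  )
  validate_lanthipeptide(s)
}

validate_lanthipeptide <- function(s) {
  res <- split_sequence(s$core_sequence)
  len <- length(res)
  bad <- setdiff(res, names(residue_formulas))
  if (length(bad) > 0) {
    stop("core sequence contains unknown residue(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  all_pos <- c(s$dehydrations, unlist(s$thioether_bridges),
               s$lysinoalanine, s$hydroxylations)
  if (length(all_pos) > 0 && (any(all_pos < 1) || any(all_pos > len))) {
    stop("modification positions must lie in 1..", len, call. = FALSE)
  }
  if (anyDuplicated(s$dehydrations)) {
    stop("duplicated dehydration positions", call. = FALSE)
  }
  if (!all(res[s$dehydrations] %in% c("S", "T"))) {
    stop("dehydration positions must carry Ser or Thr", call. = FALSE)
  }
  if (!all(res[s$hydroxylations] == "D")) {
    stop("hydroxylation positions must carry Asp", call. = FALSE)
  }
  bridge_pos <- unlist(s$thioether_bridges)
  if (anyDuplicated(bridge_pos)) {
    stop("a position participates in two thioether bridges", call. = FALSE)
  }
  for (p in s$thioether_bridges) {
    if (length(p) != 2) stop("each thioether bridge is a position pair",
                             call. = FALSE)
    is_cys <- res[p] == "C"
    if (sum(is_cys) != 1) {
      stop("thioether bridge (", paste(p, collapse = ","),
           ") must have exactly one Cys member", call. = FALSE)
    }
    partner <- p[!is_cys]
    if (!partner %in% s$dehydrations) {
      stop("non-Cys member of bridge (", paste(p, collapse = ","),
           ") must be a dehydrated Ser/Thr", call. = FALSE)
    }
  }
  if (!is.null(s$lysinoalanine)) {
    la <- s$lysinoalanine
    if (length(la) != 2) stop("lysinoalanine must be a position pair",
                              call. = FALSE)
    if (res[la[1]] != "S" || !(la[1] %in% s$dehydrations)) {
      stop("lysinoalanine donor must be a dehydrated Ser", call. = FALSE)
    }
    if (res[la[2]] != "K") {
      stop("lysinoalanine acceptor must be a Lys", call. = FALSE)
    }
    if (la[1] %in% bridge_pos) {
      stop("lysinoalanine donor cannot also be in a thioether bridge",
           call. = FALSE)
    }
  }
  s
}

#' @export
print.lanthipeptide <- function(x, ...) {
  cat("<lanthipeptide> ", x$name, "\n", sep = "")
  cat("  core:        ", x$core_sequence, " (", nchar(x$core_sequence),
      " aa)\n", sep = "")
  cat("  dehydrated:  ", paste(x$dehydrations, collapse = ", "), "\n", sep = "")
  cat("  thioethers:  ",
      paste(vapply(x$thioether_bridges,
                   function(p) paste(p, collapse = "-"), ""), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$lysinoalanine)) {
    cat("  lysinoalanine: ", paste(x$lysinoalanine, collapse = "-"), "\n",
        sep = "")
  }
  if (length(x$hydroxylations) > 0) {
    cat("  hydroxylated: ", paste(x$hydroxylations, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

n_bridges <- function(s) length(s$thioether_bridges)

#' Read and write structure configuration files
#'
#' Structures are serialised as small YAML documents with keys `name`,
#' `core_sequence`, `dehydrations`, `thioether_bridges`, `lysinoalanine`
#' and `hydroxylations`, so a new family member is a data file rather than
#' a code change. `read_structure(write_structure(s, path))` returns an
#' identical structure.
#'
#' @param path File path.
#' @param s A `lanthipeptide` object.
#' @return `read_structure()` returns a `lanthipeptide`;
#'   `write_structure()` returns `path` invisibly.
#' @export
read_structure <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("name", "core_sequence")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("structure config lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lanthipeptide(
    name = cfg$name,
    core_sequence = cfg$core_sequence,
    dehydrations = unlist(cfg$dehydrations),
    thioether_bridges = cfg$thioether_bridges,
    lysinoalanine = unlist(cfg$lysinoalanine),
    hydroxylations = unlist(cfg$hydroxylations)
  )
}

#' @rdname read_structure
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "lanthipeptide"))
  cfg <- list(
    name = s$name,
    core_sequence = s$core_sequence,
    dehydrations = as.list(s$dehydrations),
    thioether_bridges = lapply(s$thioether_bridges, as.list),
    lysinoalanine = if (!is.null(s$lysinoalanine)) as.list(s$lysinoalanine),
    hydroxylations = as.list(s$hydroxylations)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Packaged structure configurations
#'
#' The kyamicin, cinnamycin and duramycin core structures ship as YAML
#' configuration files under `inst/extdata/`. The kyamicin core sequence is
#' a transcription of the mature-structure figure of the discovery study,
#' validated by the requirement that the derived mature formula equal the
#' published C76H108N20O25S3.
#'
#' @param name One of `"kyamicin"`, `"cinnamycin"`, `"duramycin"`.
#' @return A `lanthipeptide` object.
#' @examples
#' mature_formula(kyamicin_structure())
#' @export
lanthipeptide_config <- function(name = c("kyamicin", "cinnamycin",
                                          "duramycin")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yml"), package = "lantimass",
                      mustWork = TRUE)
  read_structure(path)
}

#' @rdname lanthipeptide_config
#' @export
kyamicin_structure <- function() lanthipeptide_config("kyamicin")

#' @rdname lanthipeptide_config
#' @export
cinnamycin_structure <- function() lanthipeptide_config("cinnamycin")

#' @rdname lanthipeptide_config
#' @export
duramycin_structure <- function() lanthipeptide_config("duramycin")

#' Extract the core peptide from a precursor
#'
#' Cinnamycin-family precursor peptides carry an N-terminal leader that is
#' proteolytically removed after modification; the mature core is the
#' C-terminal stretch. No protease recognition motif is modelled: the core
#' is taken as a fixed C-terminal length (19 for this family).
#'
#' @param precursor Amino-acid string (vectorised).
#' @param core_length Number of C-terminal residues to keep.
#' @return Character vector of core sequences.
#' @examples
#' extract_core("MLEADLSVFAGG", core_length = 4)
#' @export
extract_core <- function(precursor, core_length = 19) {
  if (!is.numeric(core_length) || length(core_length) != 1 ||
      core_length < 1 || core_length != round(core_length)) {
    stop("`core_length` must be a positive integer", call. = FALSE)
  }
  len <- nchar(precursor)
  if (any(core_length > len)) {
    stop("core_length (", core_length,
         ") exceeds precursor length (", min(len), ")", call. = FALSE)
  }
  substr(precursor, len - core_length + 1, len)
}

#' Read precursor peptides from FASTA
#'
#' @param path FASTA file of amino-acid precursor sequences.
#' @return A tibble with columns `name` and `sequence`.
#' @export
read_precursors <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  tibble::tibble(name = names(seqs), sequence = unname(as.character(seqs)))
}
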