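# Published reference values for the seven species characterised in the
# kyamicin study (calculated/observed [M+2H]2+ m/z and ppm error).
table2 <- tibble::tibble(
  species = c("kyamicin", "deoxykyamicin", "kyamicin (-1S)", "kyamicin (-2S)",
              "kyamicin (-3S)", "duramycin", "deoxyduramycin"),
  formula = c("C76H108N20O25S3", "C76H108N20O24S3", "C76H110N20O25S2",
              "C76H112N20O25S", "C76H114N20O25", "C89H125N23O25S3",
              "C89H125N23O24S3"),
  mz_calc = c(899.3551, 891.3576, 884.3768, 869.3987, 854.4204,
              1006.9262, 998.9287),
  mz_obs = c(899.3553, 891.3557, 884.3767, 869.3990, 854.4202,
             1006.9232, 998.9253),
  ppm = c(0.22, -2.13, -0.11, 0.35, -0.23, -2.98, -3.40)
)

# A minimal two-bridge structure with a lysinoalanine, small enough to
# reason about by hand.
toy_structure <- function() {
  lanthipeptide(
    name = "toy",
    core_sequence = "CASTCSAK",
    dehydrations = c(4, 6),
    thioether_bridges = list(c(4, 5)),
    lysinoalanine = c(6, 8),
    hydroxylations = integer()
  )
}

# Random valid formulas for property tests.
random_formula <- function() {
  els <- sample(names(lantimass::atomic_masses), sample(1:5, 1))
  counts <- sample(0:40, length(els), replace = TRUE)
  counts[1] <- sample(1:40, 1)  # at least one element present
  ms_formula(stats::setNames(counts, els))
}

expect_formula_equal <- function(f, text) {
  expect_identical(render_formula(f), render_formula(parse_formula(text)))
}
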