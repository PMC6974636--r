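test_that("the lysinoalanine rearrangement conserves atoms", {
  ky <- kyamicin_structure()
  subs <- rearranged_residues(ky)
  expect_identical(names(subs), c("6", "19"))
  expect_formula_equal(subs[["6"]], "C2H3NO")
  expect_formula_equal(subs[["19"]], "C7H12N2O")

  # Gly + modified Lys carry exactly the atoms of the intact Dha + Lys pair
  dha <- parse_formula("C3H5NO2") - parse_formula("H2O")
  lys <- parse_formula("C6H12N2O")
  expect_formula_equal(subs[["6"]] + subs[["19"]],
                       render_formula(dha + lys))

  no_la <- lanthipeptide("plain", "GASA")
  expect_error(rearranged_residues(no_la), "no lysinoalanine")
})

test_that("y-ion ladders are monotone with residue-mass steps", {
  lad <- y_ion_ladder(kyamicin_structure())
  expect_identical(nrow(lad), 18L)
  expect_true(all(diff(lad$mz) > 0))

  # the step from y_n to y_{n+1} is the mass of the entering residue
  forms <- lapply(lad$formula, parse_formula)
  for (n in seq_len(17)) {
    entering <- forms[[n + 1]] - forms[[n]]
    expect_gt(monoisotopic_mass(entering), 50)  # a residue, not a proton
    expect_equal(lad$mz[n + 1] - lad$mz[n], monoisotopic_mass(entering),
                 tolerance = 1e-9)
  }

  # spans cutting the lysinoalanine (y1..y13) are rearranged; y14 onwards
  # contain both partners and keep the intact bridge
  expect_identical(lad$rearranged, c(rep(TRUE, 13), rep(FALSE, 5)))
  # fully reduced: no intact thioether is severed
  expect_false(any(lad$severs_thioether))
})

test_that("y1 is the rearranged lysine fragment", {
  lad <- y_ion_ladder(kyamicin_structure())
  # modified Lys residue + water, singly protonated
  y1 <- parse_formula("C7H12N2O") + parse_formula("H2O")
  expect_identical(lad$formula[1], render_formula(y1))
  expect_equal(lad$mz[1], ion_mz(y1, 1), tolerance = 1e-12)
})

test_that("the ladder is complementary to the fully reduced precursor", {
  ky <- kyamicin_structure()
  lad <- y_ion_ladder(ky, k_reduced = 3)
  full <- reduced_formula(ky, 3)
  # residue 1 is a bridge Cys reduced to Ala
  expect_formula_equal(parse_formula(lad$formula[18]) + parse_formula("C3H5NO"),
                       render_formula(full))
  # singly protonated full peptide against the published doubly charged ion
  expect_equal(monoisotopic_mass(full) + proton_mass,
               2 * 854.4204 - proton_mass, tolerance = 2e-4)
})

test_that("atom conservation holds across randomised structures", {
  base <- kyamicin_structure()
  for (s in simulate_variant_structures(base, 6, seed = 11)) {
    len <- nchar(s$core_sequence)
    full <- reduced_formula(s, 3)
    lad <- y_ion_ladder(s, k_reduced = 3)
    forms <- lantimass:::reduced_residue_formulas(s, 3, TRUE)
    subs <- rearranged_residues(s)
    la <- s$lysinoalanine
    for (n in c(1, 5, 13, 18)) {
      span_start <- len - n + 1
      prefix_forms <- forms[seq_len(span_start - 1)]
      if (la[1] < span_start && la[2] >= span_start) {
        prefix_forms[[la[1]]] <- subs[[as.character(la[1])]]
      }
      complement <- Reduce(`+`, prefix_forms, ms_formula())
      # fragment + complementary residues recover the full reduced peptide
      expect_formula_equal(parse_formula(lad$formula[n]) + complement,
                           render_formula(full))
    }
  }
})

test_that("partially reduced ladders flag fragments severing intact bridges", {
  ky <- kyamicin_structure()
  lad0 <- y_ion_ladder(ky, k_reduced = 0)
  # every span from y2 to y18 cuts at least one of the three intact bridges
  expect_true(any(lad0$severs_thioether))
  expect_false(lad0$severs_thioether[1])  # y1 (Lys19) cuts only the Lal
  expect_error(y_ion_ladder(ky, k_reduced = 5), "0\\.\\.3")
})

test_that("ladder matching finds, bounds and refuses peaks correctly", {
  ky <- kyamicin_structure()
  lad <- y_ion_ladder(ky)

  exact <- data.frame(mz = lad$mz)
  m <- match_ladder(exact, lad, tol_ppm = 5)
  expect_true(all(m$matched))
  expect_equal(max(abs(m$ppm)), 0, tolerance = 1e-9)

  set.seed(3)
  jit <- data.frame(mz = lad$mz * (1 + rnorm(18, 0, 2) / 1e6))
  mj <- match_ladder(jit, lad, tol_ppm = 10)
  expect_true(all(mj$matched))
  expect_true(all(abs(mj$ppm) <= 10))

  shifted <- data.frame(mz = lad$mz * (1 + 50 / 1e6))
  ms <- match_ladder(shifted, lad, tol_ppm = 10)
  expect_false(any(ms$matched))
  expect_true(all(is.na(ms$ppm)))

  expect_error(match_ladder(data.frame(mz = numeric()), lad), "empty")
})
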