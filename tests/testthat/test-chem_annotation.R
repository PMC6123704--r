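# Formula arithmetic, monoisotopic masses and ion annotation.

test_that("parse_formula handles counts, repeats and errors", {
  expect_equal(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_equal(parse_formula("C9H17NO5"), c(C = 9L, H = 17L, N = 1L, O = 5L))
  expect_equal(parse_formula("C3H9NO3S"), c(C = 3L, H = 9L, N = 1L, O = 3L, S = 1L))
  # repeated element mentions are summed; two-letter symbols recognized
  expect_equal(parse_formula("CH3COOH"), c(C = 2L, H = 4L, O = 2L))
  expect_equal(parse_formula("NaCl"), c(Cl = 1L, Na = 1L))
  expect_error(parse_formula("C2Xx3"), "unknown element")
  expect_error(parse_formula("c2h4"), "position 1")
  expect_error(parse_formula("H2O)"), "position")
})

test_that("formula round-trips through its canonical Hill-order string", {
  expect_equal(formula_string(parse_formula("O5NC9H17")), "C9H17NO5")
  expect_equal(formula_string(parse_formula("")), "")
  set.seed(42)
  for (i in 1:25) {
    f <- canonical_formula(random_formula())
    expect_identical(parse_formula(formula_string(f)), f)
  }
})

test_that("monoisotopic masses match NIST sums", {
  expect_identical(monoisotopic_mass(""), 0)
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6 / 18)
  expect_equal(monoisotopic_mass("C3H9NO3S"), 139.030314, tolerance = 1e-6 / 139)
  # frozen independent sums (NIST masses written out)
  expect_equal(monoisotopic_mass("C9H17NO5"),
               9 * 12 + 17 * 1.00782503207 + 14.0030740048 + 5 * 15.9949146196,
               tolerance = 1e-12)
})

test_that("mass additivity holds for random formula unions", {
  set.seed(7)
  for (i in 1:25) {
    f1 <- random_formula(); f2 <- random_formula()
    joined <- tapply(c(f1, f2), c(names(f1), names(f2)), sum)
    expect_equal(monoisotopic_mass(canonical_formula(joined)),
                 monoisotopic_mass(canonical_formula(f1)) +
                   monoisotopic_mass(canonical_formula(f2)),
                 tolerance = 1e-9 / 100)
  }
})

test_that("deprotonated m/z subtracts the proton mass and reproduces the lock mass", {
  expect_equal(deprotonated_mz(monoisotopic_mass("C3H9NO3S")), 138.0230374,
               tolerance = 1e-5 / 138)
  expect_equal(deprotonated_mz(monoisotopic_mass("C9H17NO5")), 218.103396,
               tolerance = 1e-6 / 218)
  expect_equal(deprotonated_mz(proton_mass + 1), 1, tolerance = 1e-12)
  expect_error(deprotonated_mz(0.5), "positive")
})

test_that("phenylhydrazone derivatization applies +C6H8N2 -H2O", {
  expect_equal(phenylhydrazone_formula("C3H4O3"),
               c(C = 9L, H = 10L, N = 2L, O = 2L))
  expect_equal(phenylhydrazone_formula("H2O"), c(C = 6L, H = 8L, N = 2L))
  expect_error(phenylhydrazone_formula("CO"), "derivatization")
  expect_error(phenylhydrazone_formula("C2H1O3"), "derivatization")
  # constant mass shift = mass(C6H8N2) - mass(H2O); value cross-checked
  # against rdkit ExactMolWt of phenylhydrazine and water
  shift <- monoisotopic_mass("C6H8N2") - monoisotopic_mass("H2O")
  expect_equal(shift, 90.0581836, tolerance = 1e-6 / 90)
  set.seed(11)
  for (i in 1:20) {
    f <- canonical_formula(random_formula())
    f["H"] <- max(2L, if ("H" %in% names(f)) f[["H"]] else 0L)
    f["O"] <- max(1L, if ("O" %in% names(f)) f[["O"]] else 0L)
    f <- canonical_formula(f)
    expect_equal(monoisotopic_mass(phenylhydrazone_formula(f)) - monoisotopic_mass(f),
                 shift, tolerance = 1e-9)
  }
})

test_that("ion library has one entry per metabolite plus derivatized keto acids", {
  mets <- metabolite_table(data.frame(
    id = c("m1", "m2"), name = c("a", "b"),
    formula = c("C6H14O6", "C5H9NO4"), is_keto_acid = FALSE))
  expect_equal(nrow(build_ion_library(mets)), 2L)

  mets$is_keto_acid <- c(TRUE, FALSE)
  mets$formula <- c("C3H4O3", "C5H9NO4")
  lib <- build_ion_library(metabolite_table(mets[, 1:4]))
  expect_equal(nrow(lib), 3L)
  expect_false(is.unsorted(lib$expected_mz))

  pyr <- lib[lib$metabolite_id == "m1", ]
  expect_equal(pyr$expected_mz[!pyr$derivatized],
               monoisotopic_mass("C3H4O3") - proton_mass, tolerance = 1e-12)
  # frozen from the bundled NIST masses (underivatized / phenylhydrazone)
  expect_equal(sort(pyr$expected_mz), c(87.008768, 177.066951),
               tolerance = 1e-6 / 87)
  dup <- rbind(mets, mets[1, ])
  expect_error(build_ion_library(metabolite_table(dup)), "duplicate")
})

test_that("annotation respects tolerance and the best-match rule", {
  lib <- build_ion_library(generate_metabolite_library())
  hot <- data.frame(id = "hot", name = "HOT", formula = "C3H9NO3S",
                    is_keto_acid = FALSE)
  lib2 <- build_ion_library(metabolite_table(hot))
  ann <- annotate_ions(138.023037, lib2)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$mass_error_da, 0, tolerance = 1e-6)
  expect_equal(nrow(annotate_ions(138.0275, lib2)), 0L)  # 0.0045 > 0.003

  # best match = smallest |error|; ties keep both matches, best by id
  lib3 <- data.frame(metabolite_id = c("near", "far"),
                     expected_mz = c(100.000, 100.003),
                     derivatized = FALSE)
  a <- annotate_ions(100.001, lib3)
  expect_equal(a$metabolite_id, "near")
  expect_equal(a$n_matches, 2L)
  expect_equal(a$mass_error_da, 0.001, tolerance = 1e-9)

  lib4 <- data.frame(metabolite_id = c("zeta", "alpha"),
                     expected_mz = c(99.999, 100.001),
                     derivatized = FALSE)
  a4 <- annotate_ions(100.000, lib4)
  expect_equal(a4$metabolite_id, "alpha")   # tie at |0.001|: smallest id wins
  expect_equal(a4$n_matches, 2L)
  expect_error(annotate_ions(100, lib3[0, ]), "empty")
})

test_that("fast annotation equals brute-force all-pairs matching", {
  set.seed(3)
  for (rep in 1:5) {
    lib <- data.frame(
      metabolite_id = sprintf("m%03d", 1:80),
      expected_mz = sort(runif(80, 50, 60)),
      derivatized = FALSE, stringsAsFactors = FALSE)
    ions <- runif(100, 50, 60)
    fast <- annotate_ions(ions, lib)
    slow <- brute_force_matches(ions, lib)
    n_slow <- vapply(slow, nrow, integer(1))
    expect_equal(nrow(fast), sum(n_slow > 0))
    for (k in which(n_slow > 0)) {
      row <- fast[fast$ion_mz == ions[k], ]
      expect_equal(row$n_matches, n_slow[k])
      got <- sort(strsplit(row$all_matches, ";")[[1]])
      want <- sort(sprintf("%s:%.6f", slow[[k]]$metabolite_id, slow[[k]]$mass_error))
      expect_identical(got, want)
    }
  }
})
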