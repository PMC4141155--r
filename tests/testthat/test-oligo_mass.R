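test_that("bracket notation parses with repeat expansion, both dialects", {
  s <- parse_oligo("d[(TTAGGG)4TTA]")
  expect_s3_class(s, "oligo_seq")
  expect_equal(s$alphabet, "DNA")
  expect_length(s$residues, 27)
  expect_equal(as.vector(table(s$residues)[c("T", "A", "G")]), c(10, 5, 12))

  # underscored repeat dialect expands identically
  s2 <- parse_oligo("d[(TTAGGG)_4_TTA]")
  expect_identical(s2$residues, s$residues)

  r <- parse_oligo("r[UUA]")
  expect_equal(r$alphabet, "RNA")
  expect_length(r$residues, 3)

  # parse -> format is the identity on the expanded base string
  expect_equal(format(s), paste0("d[", paste(s$residues, collapse = ""), "]"))
})

test_that("parser rejects malformed notation", {
  expect_error(parse_oligo("d[(TX)2]"), "illegal base")
  expect_error(parse_oligo("r[UUT]"), "illegal base")
  expect_error(parse_oligo("d[(TTA)0TTA]"), "repeat")
  expect_error(parse_oligo("d[(TTATTA]"), "parenthesis")
  expect_error(parse_oligo("d[TTA"), "bracket")
  expect_error(parse_oligo("d[]"), "empty")
})

test_that("strand composition matches an independent per-atom oracle", {
  # thymidine: residue + H2O - HPO3
  expect_equal(format(oligo_composition("d[T]")), "C10H14N2O5")

  # full 27-mer against a formula-string token-count oracle
  residue_formulas <- c(rep("C10H13N2O7P", 10),  # dT x10
                        rep("C10H12N5O5P", 5),   # dA x5
                        rep("C10H12N5O6P", 12),  # dG x12
                        "H2O")                   # termini
  expected <- count_atoms_oracle(residue_formulas)
  expected["H"] <- expected["H"] - 1             # minus HPO3 (5'-OH)
  expected["P"] <- expected["P"] - 1
  expected["O"] <- expected["O"] - 3
  got <- oligo_composition(dna_27mer)
  expect_equal(unclass(got)[order(names(got))],
               expected[order(names(expected))])
  expect_equal(format(got), "C270H335N105O165P26")

  # concatenation identity: comp(ab) = comp(a) + comp(b) - H2O + HPO3
  lhs <- oligo_composition("d[TT]")
  rhs <- oligo_composition("d[T]") + oligo_composition("d[T]") -
    elem_comp(H = 2, O = 1) + elem_comp(H = 1, P = 1, O = 3)
  expect_equal(unclass(lhs), unclass(rhs))
})

test_that("average masses reproduce the printed strand masses", {
  expect_equal(average_mass(elem_comp(H = 2, O = 1)), 18.015, tolerance = 1e-9)
  expect_lt(abs(average_mass(dna_27mer) - 8496.6), 0.1)
  expect_lt(abs(average_mass(rna_27mer) - 8788.3), 0.1)
  # 5'-phosphate flag adds one HPO3
  withp <- average_mass(parse_oligo(dna_27mer, five_prime_phosphate = TRUE))
  expect_equal(withp - average_mass(dna_27mer),
               average_mass(elem_comp(H = 1, P = 1, O = 3)),
               tolerance = 1e-9)
})

test_that("monoisotopic masses are exact and below average masses", {
  expect_equal(monoisotopic_mass(elem_comp(H = 2, O = 1)), 18.0106,
               tolerance = 1e-4)
  expect_equal(monoisotopic_mass(elem_comp(C = 1)), 12.0)
  # frozen from per-isotope summation: 10*12 + 14*1.0078250319 +
  #   2*14.0030740052 + 5*15.9949146221
  expect_equal(monoisotopic_mass("d[T]"), 242.0902715, tolerance = 1e-6)
  set.seed(7)
  for (i in 1:20) {
    comp <- random_composition()
    if (any(c("C", "N", "O") %in% names(comp)))
      expect_lt(monoisotopic_mass(comp), average_mass(comp))
  }
  expect_error(average_mass(elem_comp(Xx = 1)), "unknown element")
})

test_that("built-in molecules carry the expected masses and charges", {
  m <- builtin_molecules()
  expect_lt(abs(m$TMPyP4$average_mass - 678.8), 0.1)
  expect_lt(abs(m$tosylate$average_mass - 171.2), 0.1)
  expect_lt(abs(m$ammonium$average_mass - 18.04), 0.01)
  expect_equal(m$TMPyP4$intrinsic_charge, 4L)
  expect_equal(m$tosylate$intrinsic_charge, -1L)
  expect_equal(m$ammonium$intrinsic_charge, 1L)
})

test_that("composition arithmetic is commutative, associative, closed", {
  set.seed(11)
  for (i in 1:25) {
    a <- random_composition(); b <- random_composition()
    cc <- random_composition()
    expect_equal(unclass(a + b), unclass(b + a))
    expect_equal(unclass((a + b) + cc), unclass(a + (b + cc)))
    expect_equal(unclass((a + b) - b), unclass(a))
  }
  expect_error(elem_comp(C = 1) - elem_comp(C = 2), "negative")
})
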