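test_that("backbone parsing splits arms at the single gamma turn", {
  pa <- parse_backbone("Ac-NH-PyPyPyPyβPyPyPy-γ-ImImβImImPy-COOH",
                       tail = "IndoleSecoCBI", name = "CCC-003")
  expect_equal(pa$arm1, c("Py", "Py", "Py", "Py", "Beta", "Py", "Py", "Py"))
  expect_equal(pa$arm2, c("Im", "Im", "Beta", "Im", "Im", "Py"))
  expect_equal(pa$cap, "AcCap")
  expect_equal(pa$tail, "IndoleSecoCBI")

  mini <- parse_backbone("Py-γ-Py")
  expect_equal(mini$arm1, "Py")
  expect_equal(mini$arm2, "Py")
  expect_null(mini$cap)
  expect_null(mini$tail)

  # plain-text aliases for the Greek letters
  alias <- parse_backbone("Ac-NH-PyPyPyPybPyPyPy-g-ImImbImImPy-COOH")
  expect_equal(alias$arm1, pa$arm1)
  expect_equal(alias$arm2, pa$arm2)
})

test_that("backbone parsing rejects unknown tokens and bad turn counts", {
  expect_error(parse_backbone("PyPyXxPy-γ-Im"), "Xx")
  expect_error(parse_backbone("PyPy-ImIm"), "exactly one")
  expect_error(parse_backbone("Py-γ-Py-γ-Im"), "exactly one")
  expect_error(hairpin_polyamide("Py", c("Py", "Im")), "geometry")
})

test_that("parse_backbone inverts format_backbone on random hairpins", {
  set.seed(41)
  for (i in 1:25) {
    pa <- random_backbone()
    back <- parse_backbone(format_backbone(pa))
    expect_equal(back[c("arm1", "arm2", "cap", "tail")],
                 pa[c("arm1", "arm2", "cap", "tail")])
  }
})

test_that("derive_motif reproduces the printed CCC-003 recognition motif", {
  pa <- parse_backbone("Ac-NH-PyPyPyPyβPyPyPy-γ-ImImβImImPy-COOH",
                       tail = "IndoleSecoCBI")
  m <- derive_motif(pa)
  expect_identical(m$iupac, "WGGWGGWWWA")
  expect_identical(m$alkylation_index, 9L)
})

test_that("derive_motif applies the ring-pair rules on small hairpins", {
  expect_identical(derive_motif(parse_backbone("Py-γ-Py"))$iupac, "WW")
  # Py/Im pairs read G on the arm2 strand
  m <- derive_motif(hairpin_polyamide(c("Py", "Py"), c("Im", "Im")))
  expect_identical(m$iupac, "WGG")
  expect_null(m$alkylation_index)
})

test_that("derived motif length follows the closed form and alkylation sits on A", {
  set.seed(42)
  for (i in 1:40) {
    pa <- random_backbone()
    m <- derive_motif(pa)
    n1 <- length(pa$arm1); n2 <- length(pa$arm2)
    overhang <- n1 - n2
    tail_pos <- if (identical(pa$tail, "IndoleSecoCBI"))
      max(0L, 2L - overhang) + 1L else 0L
    expect_equal(nchar(m$iupac), 1L + n2 + overhang + tail_pos)
    if (identical(pa$tail, "IndoleSecoCBI")) {
      expect_identical(substr(m$iupac, nchar(m$iupac), nchar(m$iupac)), "A")
      expect_identical(m$alkylation_index, nchar(m$iupac) - 1L)
    } else {
      expect_null(m$alkylation_index)
    }
  }
})

test_that("molecular formulas parse, canonicalize and round-trip", {
  f <- parse_formula("C102H105ClN34O18")
  expect_equal(unclass(f)[c("C", "H", "Cl", "N", "O")],
               c(C = 102L, H = 105L, Cl = 1L, N = 34L, O = 18L))
  expect_equal(unclass(parse_formula("C"))[["C"]], 1L)
  expect_equal(unclass(parse_formula("H2O")), c(H = 2L, O = 1L),
               ignore_attr = TRUE)
  expect_identical(format_formula(f), "C102H105ClN34O18")
  set.seed(43)
  for (i in 1:10) {
    sym <- sample(c("C", "H", "N", "O", "S", "Cl", "Na"), sample(2:5, 1))
    cnt <- sample(1:120, length(sym), replace = TRUE)
    f1 <- parse_formula(paste0(sym, cnt, collapse = ""))
    expect_equal(unclass(parse_formula(format_formula(f1))), unclass(f1))
  }
  expect_error(parse_formula("Qq3"), "unknown element")
  expect_error(parse_formula("C0"), "zero")
})

test_that("monoisotopic masses match reference values and are additive", {
  expect_identical(monoisotopic_mass(parse_formula("C")), 12)
  expect_equal(round_half_up(monoisotopic_mass(parse_formula("H2O")), 4),
               18.0106)
  # conjugate QC value: neutral monoisotopic mass reported at 2 decimals
  f <- parse_formula("C102H105ClN34O18")
  expect_equal(round_half_up(monoisotopic_mass(f), 2), 2128.80)
  # additivity
  set.seed(44)
  for (i in 1:10) {
    a <- parse_formula(paste0("C", sample(1:50, 1), "H", sample(1:80, 1)))
    b <- parse_formula(paste0("N", sample(1:20, 1), "O", sample(1:20, 1)))
    ab <- parse_formula(paste0(format_formula(a), format_formula(b)))
    expect_equal(monoisotopic_mass(ab),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-9)
  }
})

test_that("protonated m/z adds exactly one proton mass", {
  expect_equal(protonated_mz(parse_formula("C")), 13.007276)
  expect_equal(round_half_up(protonated_mz(parse_formula("H2O")), 4),
               19.0178)  # 18.010565 + 1.007276 at full precision
  f <- parse_formula("C102H105ClN34O18")
  expect_equal(protonated_mz(f), monoisotopic_mass(f) + 1.007276)
})

test_that("the bundled compound registry carries the three screen motifs", {
  reg <- load_compound_registry()
  expect_identical(reg[["KR12"]]$iupac, "WCGCCWWCA")
  expect_identical(reg[["CCC-002"]]$iupac, "WGGCWCCCA")
  expect_identical(reg[["CCC-003"]]$iupac, "WGGWGGWWWA")
  expect_identical(reg[["KR12"]]$alkylation_index, 8L)
  expect_identical(reg[["CCC-003"]]$alkylation_index, 9L)
})
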