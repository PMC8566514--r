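test_that("formula parsing handles multiplicities, round-trips and rejects garbage", {
  f <- parseFormula("C19H14BrClN6O2")
  expect_identical(elementCounts(f),
                   c(C = 19L, H = 14L, Br = 1L, Cl = 1L, N = 6L, O = 2L))
  expect_identical(elementCounts(parseFormula("H")), c(H = 1L))
  expect_identical(elementCounts(parseFormula("C6H10O5")),
                   c(C = 6L, H = 10L, O = 5L))
  ## round-trip through formatting for every fixture formula
  for (fs in fixtureTable$formula)
    expect_identical(formatFormula(parseFormula(fs)), fs)
  expect_error(parseFormula("C6H10X5"), "unknown element")
  expect_error(parseFormula("Xx2"), "unknown element")
  expect_error(parseFormula("C0H4"), "malformed multiplier")
  expect_error(parseFormula(""), "nzchar")
})

test_that("monoisotopic mass is additive and matches known values", {
  expect_equal(roundHalfUp(monoisotopicMass("C6H10O5"), 4), 162.0528)
  expect_equal(roundHalfUp(monoisotopicMass("C6H10O5"), 2), 162.05)
  ## independently hand-summed from the NIST monoisotopic masses
  expect_equal(roundHalfUp(monoisotopicMass("C19H14BrClN6O2"), 4), 472.0050)
  ## additivity: mass(f) + mass(g) = mass(f + g)
  set.seed(42)
  for (i in 1:20) {
    cnt1 <- sample(0:8, 7, replace = TRUE)
    cnt2 <- sample(0:8, 7, replace = TRUE)
    cnt1[1] <- cnt1[1] + 1L; cnt2[2] <- cnt2[2] + 1L
    f <- do.call(newFormula, as.list(setNames(cnt1, supportedElements())))
    g <- do.call(newFormula, as.list(setNames(cnt2, supportedElements())))
    expect_equal(monoisotopicMass(f) + monoisotopicMass(g),
                 monoisotopicMass(addFormulas(f, g)), tolerance = 1e-12)
  }
})

test_that("protonated-cation m/z reproduces accurate-mass reference values", {
  expect_equal(roundHalfUp(cationMz("C19H14BrClN6O2"), 4), 473.0123)
  expect_equal(roundHalfUp(cationMz("C19H12BrClN6O"), 4), 455.0017)
  expect_equal(roundHalfUp(cationMz("C24H20BrClN6O7"), 4), 619.0338)
  expect_equal(roundHalfUp(cationMz("C9H5BrClN3O2"), 4), 301.9326)
  expect_error(cationMz("C6H10O5", adduct = "M+Na"), "unsupported adduct")
  ## electron mass must be subtracted: without it the parent comes out at
  ## 473.0128, which does not match accurate-mass practice
  expect_lt(cationMz("C19H14BrClN6O2"),
            monoisotopicMass("C19H14BrClN6O2") + monoisotopicMass("H"))
})

test_that("ppm error is signed, zero on identity, and matches printed precision", {
  expect_equal(roundHalfUp(ppmError(455.0022, 455.0017), 1), 1.1)
  expect_equal(roundHalfUp(ppmError(651.0616, 651.0600), 1), 2.5)
  expect_identical(ppmError(473.0126, 473.0126), 0)
  expect_equal(ppmError(473.0126 * (1 + 5e-6), 473.0126), 5, tolerance = 1e-9)
  expect_error(ppmError(100, -1))
})

test_that("RDBE and nitrogen rule behave as valence arithmetic requires", {
  expect_equal(rdbe("C19H14BrClN6O2"), 15)
  expect_equal(rdbe("CH4"), 0)
  expect_equal(rdbe("C6H10O5"), 2)
  expect_true(nitrogenRuleOk("NH3"))
  expect_true(nitrogenRuleOk("C19H14BrClN6O2"))
  expect_false(nitrogenRuleOk("C2H5N2"))  # odd nominal mass, even N
  for (fs in fixtureTable$formula) expect_true(nitrogenRuleOk(fs))
})

test_that("isotopologue patterns match printed halogen reference ions", {
  p <- isotopologuePattern("C19H14BrClN6O2")
  cl <- clusters(p)
  a2 <- cl[cl$nominal_shift == 2, ][1, ]  # halogen sub-cluster comes first
  a4 <- cl[cl$nominal_shift == 4, ][1, ]
  expect_lt(abs(a2$mz - 475.010), 0.001)
  expect_lt(abs(a4$mz - 477.007), 0.001)
  ## printed reference ions reproduce at 4 dp from the cluster centroids
  expect_equal(roundHalfUp(a2$mz, 4), 475.0100, tolerance = 1e-9)
  expect_equal(roundHalfUp(a4$mz, 4), 477.0073, tolerance = 1e-9)
  ## base cluster is the A+2 (one Br + one Cl makes A+2 the tallest peak)
  expect_equal(max(cl$abundance), 100)
  expect_equal(cl$abundance[cl$nominal_shift == 2][1], 100)
})

test_that("a single carbon gives the textbook ~1.1% A+1 satellite", {
  cl <- clusters(isotopologuePattern("CH4"))
  expect_equal(cl$abundance[1], 100)
  a1 <- cl$abundance[cl$nominal_shift == 1]
  expect_gt(a1, 1.0)
  expect_lt(a1, 1.3)
})

test_that("one Br plus one Cl yields the diagnostic A+2/A ratio and an A+4", {
  set.seed(7)
  for (i in 1:8) {
    f <- newFormula(C = sample(1:20, 1), H = sample(1:20, 1),
                    N = sample(0:4, 1) * 2, O = sample(0:6, 1),
                    Br = 1, Cl = 1)
    cl <- clusters(isotopologuePattern(f))
    a <- cl$abundance[cl$nominal_shift == 0][1]
    a2 <- cl$abundance[cl$nominal_shift == 2][1]
    expect_gte(a2 / a, 1.25)
    expect_lte(a2 / a, 1.35)
    expect_true(any(cl$nominal_shift == 4))
  }
})

test_that("total isotopologue probability is conserved", {
  for (fs in c("C19H14BrClN6O2", "C25H25BrClN5O9", "CH4", "C22H18BrClN6O4S")) {
    pk <- isotopePeaks(fs)
    expect_lt(abs(sum(pk$prob) - 1), 1e-9)
    expect_lt(abs(isotopologuePattern(fs)@rawTotal - 1), 1e-9)
  }
})

test_that("convolution equals brute-force multinomial enumeration on small formulas", {
  smalls <- c("CH4", "NH3", "H2O", "CO2", "CH3Cl", "CH2BrCl", "C2H5Br",
              "SO2", "H2S", "C3H4ClN", "C2H2Cl2", "C4H6O2")
  for (fs in smalls) {
    fast <- isotopePeaks(fs)
    agg <- rowsum(fast$prob, round(fast$mz, 7))
    fast <- data.frame(mz = as.numeric(rownames(agg)), prob = agg[, 1])
    oracle <- oracleIsotopePeaks(fs)
    merged <- merge(fast, oracle, by = "mz", all = TRUE)
    merged$prob.x[is.na(merged$prob.x)] <- 0
    merged$prob.y[is.na(merged$prob.y)] <- 0
    expect_lt(max(abs(merged$prob.x - merged$prob.y)), 1e-6,
              label = paste("max abundance deviation for", fs))
  }
})

test_that("the embedded isotope table carries the expected constants", {
  tab <- isotopeTable()
  cl35 <- tab[tab$isotope == "35Cl", ]
  expect_equal(cl35$abundance, 0.7576)
  expect_equal(tab[tab$isotope == "79Br", "abundance"], 0.5069)
  expect_equal(tab[tab$isotope == "13C", "abundance"], 0.0107)
  expect_equal(electronMass(), 0.000548579909)
})
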