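test_that("enumeration recovers known assignments from observed masses", {
  cand <- enumerateFormulas(473.0126)
  expect_true("C19H14BrClN6O2" %in% cand$formula)
  cand <- enumerateFormulas(651.0616)
  expect_true("C25H24BrClN6O8" %in% cand$formula)
  ## every reported candidate respects the advertised constraints
  expect_true(all(abs(cand$ppm) <= 5))
  expect_true(all(cand$rdbe >= 0 & cand$rdbe <= 40))
  expect_identical(cand$rank, seq_len(nrow(cand)))
})

test_that("enumeration of an infeasible mass is empty, not an error", {
  expect_identical(nrow(enumerateFormulas(10.0)), 0L)
})

test_that("enumeration equals a nested-loop brute force on reduced bounds", {
  small <- elementBounds(C = c(0, 10), H = c(0, 16), N = c(0, 4),
                         O = c(0, 4), S = c(0, 4), Cl = c(0, 4),
                         Br = c(0, 4))
  for (mz in c(160.9899, 221.0, 301.9328, 180.05)) {
    for (halo in c(TRUE, FALSE)) {
      fast <- sort(enumerateFormulas(mz, tol = 10, bounds = small,
                                     requireHalogen = halo)$formula)
      slow <- bruteForceFormulas(mz, tol = 10, bounds = small,
                                 requireHalogen = halo)
      expect_identical(fast, slow,
                       label = paste("mz", mz, "halogen", halo))
    }
  }
})

test_that("widening tolerance or bounds never removes a candidate", {
  narrow <- enumerateFormulas(473.0126, tol = 2)$formula
  wide <- enumerateFormulas(473.0126, tol = 5)$formula
  expect_true(all(narrow %in% wide))
  b1 <- elementBounds(C = c(0, 20), H = c(0, 30))
  b2 <- elementBounds()
  expect_true(all(enumerateFormulas(455.0022, bounds = b1)$formula %in%
                    enumerateFormulas(455.0022, bounds = b2)$formula))
})

test_that("enumeration is deterministic", {
  a <- enumerateFormulas(489.0078)
  b <- enumerateFormulas(489.0078)
  expect_identical(a, b)
})

test_that("isotope-fit scoring rewards matching patterns and punishes a missing A+2", {
  theo <- isotopologuePattern("C19H14BrClN6O2")
  expect_equal(scoreIsotopeFit(theo, theo), 1)
  ## rescaling invariance
  obs <- clusters(theo)
  obs$abundance <- obs$abundance * 7.3
  expect_equal(scoreIsotopeFit(obs, theo), 1)
  ## the printed reference triplet against the simulated pattern
  triplet <- data.frame(mz = c(473.0123, 475.0101, 477.0074),
                        abundance = c(77, 100, 24))
  expect_gt(scoreIsotopeFit(triplet, theo), 0.9)
  ## a Br/Cl compound whose observed pattern lacks the A+2 base cluster
  theoSmall <- isotopologuePattern("CH2BrCl")
  cls <- clusters(theoSmall)
  noA2 <- cls[cls$nominal_shift != 2, ]
  expect_lt(scoreIsotopeFit(noA2, theoSmall), 0.5)
})

test_that("an observed pattern can rank candidates via the isotope score", {
  obs <- isotopologuePattern("C19H14BrClN6O2")
  cand <- enumerateFormulas(473.0126, observedPattern = obs)
  expect_true(all(cand$isotope_score >= 0 & cand$isotope_score <= 1))
  target <- cand[cand$formula == "C19H14BrClN6O2", ]
  expect_gt(target$isotope_score, 0.9)
})
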