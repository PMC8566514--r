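test_that("neutral-loss and characteristic-ion rules explain MS2 spectra", {
  rules <- loadFragmentRules(compound = "TP651a")
  ## glycoside: fragment at precursor minus anhydroglucose
  res <- matchFragments(c(489.01), 651.0608, rules)
  expect_true(any(grepl("anhydroglucose", res$matches$label)))
  loss <- res$matches[grepl("anhydroglucose", res$matches$label), ]
  expect_lt(abs(651.0608 - 162.0528 - loss$observed_mz[1]),
            651.0608 * 10e-6)
  ## parent characteristic ions
  rulesP <- loadFragmentRules(compound = "Cyantraniliprole")
  res2 <- matchFragments(c(284, 442), 473.0126, rulesP)
  ions <- res2$matches[res2$matches$kind == "characteristic_ion", ]
  expect_identical(nrow(ions), 2L)
  expect_identical(length(res2$unmatched), 0L)
  ## an unexplainable peak is reported, not dropped
  res3 <- matchFragments(50.0, 473.0126, rulesP)
  expect_identical(nrow(res3$matches), 0L)
  expect_identical(res3$unmatched, 50.0)
  ## empty spectrum is an empty match, not an error
  expect_identical(nrow(matchFragments(numeric(0), 473.0126,
                                       rulesP)$matches), 0L)
})

test_that("the precursor gate rejects spectra far from the candidate mass", {
  rules <- loadFragmentRules(compound = "Cyantraniliprole")
  expect_error(matchFragments(284, 474.0, rules, candidateMz = 473.0123),
               "outside")
  expect_silent(matchFragments(284, 473.013, rules,
                               candidateMz = 473.0123))
})

test_that("every neutral-loss match satisfies the fragment arithmetic", {
  rules <- loadFragmentRules()
  set.seed(3)
  for (i in 1:10) {
    prec <- runif(1, 300, 700)
    frag <- prec - rules$mz_or_mass[rules$kind == "neutral_loss"]
    res <- matchFragments(frag, prec, rules, mzTolPpm = 10)
    nl <- res$matches[res$matches$kind == "neutral_loss", ]
    lossOf <- setNames(rules$mz_or_mass, rules$label)
    expect_true(all(abs(prec - lossOf[nl$label] - nl$observed_mz) <=
                      prec * 10e-6))
  }
})

test_that("confidence levels follow the screening evidence hierarchy", {
  expect_identical(assignConfidence(TRUE, TRUE, TRUE), "1")
  expect_identical(assignConfidence(TRUE, FALSE, TRUE), "2b")
  expect_identical(assignConfidence(TRUE, FALSE, FALSE), "3")
  expect_identical(assignConfidence(FALSE, FALSE, TRUE), "5")
  ## fragments are a precondition for anything better than level 5
  expect_identical(assignConfidence(FALSE, TRUE, TRUE), "5")
  ## vectorized over a hit table
  lv <- assignConfidence(c(TRUE, TRUE, FALSE), FALSE, c(TRUE, FALSE, TRUE))
  expect_identical(lv, c("2b", "3", "5"))
})

test_that("the packaged evidence flags reproduce the curated confidence column", {
  lv <- assignConfidence(lengths(fixtureTable$fragment_ions) > 0,
                         fixtureTable$has_standard,
                         fixtureTable$previously_reported)
  expect_identical(lv, fixtureTable$level)
})

test_that("pathway classification separates phases and breakdown products", {
  edges <- loadPathwayEdges()
  expect_identical(classifyPhase("TP619", edges), "phase_II")
  expect_identical(classifyPhase("IN-DBC80", edges), "breakdown")
  expect_identical(classifyPhase("IN-J9Z38", edges), "phase_I")
  ## conjugation after cleavage would still be breakdown; conjugation that
  ## is not terminal does not make a phase-II product
  expect_identical(classifyPhase("IN-MLA84", edges), "phase_I")
  expect_identical(classifyPhase("Cyantraniliprole", edges), "parent")
  expect_identical(classifyPhase("TP999", edges), "unclassified")
  ph <- classifyPhase(fixtureTable$name, edges)
  expect_equal(as.integer(table(ph)[c("phase_I", "phase_II", "breakdown")]),
               c(11L, 6L, 4L))
  expect_identical(ph, fixtureTable$phase)
})
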