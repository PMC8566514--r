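feat <- function(mz, rt, area = 1e6, snr = 100, sample_id = "s1") {
  data.frame(sample_id = sample_id, mz = mz, rt = rt, area = area, snr = snr,
             stringsAsFactors = FALSE)
}

test_that("control elimination removes shared signals and logs them", {
  trt <- feat(473.0126, 9.31)
  ctl <- feat(473.0127, 9.31, sample_id = "c1")
  out <- subtractControl(trt, ctl)
  expect_identical(nrow(out), 0L)
  aud <- screenAudit(out)
  expect_identical(aud$reason, "matched_control")
  expect_equal(aud$mz, 473.0126)
  ## no match outside tolerance
  out2 <- subtractControl(trt, feat(460.0, 9.31, sample_id = "c1"))
  expect_identical(nrow(out2), 1L)
  ## retention time discriminates as much as mass does
  out3 <- subtractControl(trt, feat(473.0127, 9.55, sample_id = "c1"))
  expect_identical(nrow(out3), 1L)
})

test_that("fold-change mode keeps strongly enriched treated features", {
  trt <- feat(473.0126, 9.31, area = 1e7)
  ctl <- feat(473.0126, 9.31, area = 1e5, sample_id = "c1")
  expect_identical(nrow(subtractControl(trt, ctl)), 0L)
  expect_identical(nrow(subtractControl(trt, ctl, mode = "fold_change")), 1L)
  expect_identical(nrow(subtractControl(feat(473.0126, 9.31, area = 5e5),
                                        ctl, mode = "fold_change")), 0L)
})

test_that("intensity and signal-to-noise thresholds apply with a strict S/N cut", {
  f <- rbind(feat(400, 5, area = 9999, snr = 50),
             feat(401, 5, area = 1e6, snr = 10.0),
             feat(402, 5, area = 1e6, snr = 11))
  out <- applyThresholds(f)
  expect_equal(out$mz, 402)
  expect_identical(nrow(screenAudit(out)), 2L)
})

test_that("the halogen filter keeps Br/Cl clusters and rejects carbon satellites", {
  brcl <- feat(473.012, 9.31)
  brcl$cluster <- I(list(data.frame(mz = c(473.012, 475.010, 477.007),
                                    abundance = c(100, 129, 42))))
  conly <- feat(300.100, 5.0)
  conly$cluster <- I(list(data.frame(mz = c(300.100, 301.103),
                                     abundance = c(100, 18))))
  bare <- feat(350.05, 6.0)
  bare$cluster <- I(list(data.frame(mz = numeric(0),
                                    abundance = numeric(0))))
  out <- halogenFilter(rbind(brcl, conly, bare))
  expect_equal(out$mz, 473.012)
  aud <- screenAudit(out)
  expect_setequal(aud$reason, c("no_A2_companion", "no_isotope_cluster"))
})

test_that("suspect matching respects mass and retention-time tolerances", {
  sus <- data.frame(name = c("IN-J9Z38", "IN-MLA84", "TP441"),
                    formula = c("C19H12BrClN6O", "C18H10BrClN6O",
                                "C18H10BrClN6O"),
                    expected_mz = c(455.0017, 440.9861, 440.9861),
                    expected_rt = c(11.04, 10.27, 8.42),
                    stringsAsFactors = FALSE)
  m <- matchSuspects(feat(455.0022, 11.04), sus)
  expect_identical(m$name, "IN-J9Z38")
  expect_equal(roundHalfUp(m$ppm, 1), 1.1)
  ## isobaric suspects separate by retention time
  m2 <- matchSuspects(feat(440.9865, 8.42), sus)
  expect_identical(m2$name, "TP441")
  expect_identical(nrow(matchSuspects(feat(999.9, 5), sus)), 0L)
})

test_that("inclusion lists merge near-isobaric candidates and sort ascending", {
  expect_identical(nrow(buildInclusionList(c(473.0126, 473.0127))), 1L)
  incl <- buildInclusionList(vapply(fixtureTable$formula, cationMz,
                                    numeric(1)))
  expect_lte(nrow(incl), 21L)  # the two isobaric pairs merge
  expect_identical(nrow(incl), 20L)
  expect_false(is.unsorted(incl$mz, strictly = TRUE))
  expect_identical(nrow(buildInclusionList(numeric(0))), 0L)
})

test_that("feature detection groups frames by ppm and scores apex S/N", {
  frames <- rbind(
    data.frame(rt = c(9.26, 9.31, 9.36), mz = 473.0126 * (1 + c(-5e-7, 0, 5e-7)),
               intensity = c(6e5, 1e6, 5e5)),
    data.frame(rt = c(11.0, 11.04), mz = c(455.0022, 455.0023),
               intensity = c(2e5, 4e5)),
    data.frame(rt = rep(9.31, 40), mz = seq(472.6, 473.4, length.out = 40),
               intensity = rep(100, 40)))
  f <- detectFeatures(frames)
  main <- f[f$area >= 2e5, ]
  expect_identical(nrow(main), 2L)
  expect_equal(main$area, c(4e5, 1e6))
  expect_equal(main$rt, c(11.04, 9.31))
  big <- main[main$area == 1e6, ]
  expect_equal(big$snr, 1e6 / 100)
  expect_lt(abs(big$mz - 473.0126), 0.001)
})

test_that("screening stages are order-invariant and monotone", {
  set.seed(11)
  f <- feat(mz = runif(30, 150, 1200), rt = runif(30, 1, 12),
            area = 10^runif(30, 3, 7), snr = runif(30, 1, 200))
  a <- applyThresholds(f)
  perm <- f[sample(nrow(f)), ]
  b <- applyThresholds(perm)
  key <- function(d) d[order(d$mz), c("mz", "rt", "area", "snr")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
  expect_lte(nrow(a), nrow(f))
  ctl <- feat(mz = f$mz[1:10] * (1 + 1e-7), rt = f$rt[1:10],
              sample_id = "c1")
  s <- subtractControl(f, ctl)
  expect_lte(nrow(s), nrow(f))
  expect_identical(nrow(s) + nrow(screenAudit(s)), nrow(f))
})
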