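test_that("the same seed reproduces the study bit for bit", {
  cfg <- scaledStudyConfig()
  a <- simulateStudy(cfg, seed = 13)
  b <- simulateStudy(cfg, seed = 13)
  expect_identical(studySamples(a), studySamples(b))
  expect_identical(groundTruth(a), groundTruth(b))
  expect_identical(studyFeatures(a)$mz, studyFeatures(b)$mz)
  expect_identical(studyFeatures(a)$area, studyFeatures(b)$area)
  c <- simulateStudy(cfg, seed = 14)
  expect_false(identical(studyFeatures(a)$area, studyFeatures(c)$area))
})

test_that("xylem kinetics peak early and decline to a small fraction", {
  cfg <- studyConfig()
  x <- cfg$tissues$xylem_sap
  conc <- kineticProfile(x$dats, x$amplitude, x$tau, x$growthDilution)
  expect_true(x$dats[which.max(conc)] %in% c(7, 14))
  expect_lt(conc[length(conc)] / max(conc), 0.15)
  ## metabolite fractions stay below 10% of parent through 28 DAT
  frac28 <- cfg$fractions * (28 / 84)^cfg$fractionExponent
  expect_true(all(frac28 < 0.10))
})

test_that("a degenerate noise-free config yields exactly the parent clusters", {
  cfg <- studyConfig(nReplicates = 1, tissues = "mature_leaves",
                     peakRsd = 0, biologicalRsd = 0, mzJitterPpm = 0,
                     rtJitterMin = 0, matrixFeatureCount = 0)
  cfg$tissues$mature_leaves$dats <- 28
  cfg$tissues$mature_leaves$recoverySd <- 0
  cfg$fractions <- cfg$fractions[0]
  cfg$clusterAbundanceRsd <- 0
  st <- simulateStudy(cfg, seed = 1)
  f <- studyFeatures(st)
  trt <- f[startsWith(f$sample_id, "t_"), ]
  expect_identical(nrow(trt), 1L)
  expect_identical(trt$compound, "Cyantraniliprole")
  expect_equal(trt$mz, cationMz("C19H14BrClN6O2"), tolerance = 1e-9)
  theo <- clusters(isotopologuePattern("C19H14BrClN6O2", prune = 1))
  expect_equal(trt$cluster[[1]]$mz, theo$mz, tolerance = 1e-9)
  expect_equal(trt$cluster[[1]]$abundance, theo$abundance,
               tolerance = 1e-9)
  ## control samples carry nothing in this config
  ctl <- f[startsWith(f$sample_id, "c_"), ]
  expect_identical(nrow(ctl), 0L)
})

test_that("planted metabolite-to-parent fractions are recovered by the pipeline", {
  cfg <- scaledStudyConfig()
  st <- simulateStudy(cfg, seed = 21)
  hits <- screenStudy(st)
  mp <- mpRatios(studyTableFromHits(hits))
  ratioNoise <- sqrt(2) * cfg$peakRsd
  for (tn in names(cfg$tissues)) {
    for (dat in cfg$tissues[[tn]]$dats) {
      planted <- cfg$fractions * (dat / 84)^cfg$fractionExponent
      planted <- planted[planted >= 0.01]
      for (nm in names(planted)) {
        row <- mp[mp$compound == nm & mp$tissue == tn & mp$dat == dat, ]
        expect_identical(nrow(row), 1L)
        expect_lt(abs(row$mp_ratio_pct - planted[[nm]] * 100),
                  3 * ratioNoise * planted[[nm]] * 100)
      }
    }
  }
})

test_that("rendered spectra contain the planted isotope triplet and fragments", {
  cfg <- studyConfig(nReplicates = 1, tissues = "mature_leaves",
                     matrixFeatureCount = 5)
  cfg$tissues$mature_leaves$dats <- 84
  st <- simulateStudy(cfg, seed = 31)
  sid <- studySamples(st)$sample_id[studySamples(st)$group == "treated"][1]
  set.seed(31)
  sp <- renderSpectra(st, sid)
  ## the parent appears as its Br/Cl triplet in the MS1 frames
  for (ref in c(473.01, 475.01, 477.01))
    expect_true(any(abs(sp$frames$mz - ref) < 0.01))
  ## feature detection on the rendered frames recovers the parent
  feats <- detectFeatures(sp$frames)
  feats <- feats[order(-feats$area), ]
  i <- which(abs(feats$mz - cationMz("C19H14BrClN6O2")) < 0.01)
  expect_gte(length(i), 1L)
  expect_gt(feats$snr[i[1]], 10)
  ## glycoside MS2 contains the hydroxylated-parent fragment near
  ## precursor minus anhydroglucose
  titles <- vapply(sp$ms2, `[[`, "", "title")
  tp651 <- sp$ms2[[grep("^TP651a", titles)[1]]]
  expect_true(any(abs(tp651$peaks$mz -
                        (651.06 - 162.05)) < 0.05))
  ## unknown sample is an explicit error
  expect_error(renderSpectra(st, "nope"), "unknown sample")
})

test_that("a noise-only sample produces no suspect hits downstream", {
  cfg <- studyConfig(nReplicates = 1, tissues = "mature_leaves",
                     matrixFeatureCount = 30)
  cfg$tissues$mature_leaves$dats <- 28
  st <- simulateStudy(cfg, seed = 41)
  samp <- studySamples(st)
  feats <- studyFeatures(st)
  ctl <- feats[feats$sample_id %in%
                 samp$sample_id[samp$group == "control"], ]
  hits <- matchSuspects(ctl, suspectList())
  expect_identical(nrow(hits), 0L)
})
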