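#' @include chem.R screen.R io.R
NULL

#' Single-peak uptake kinetic profile
#'
#' Residue concentration over time for a soil-applied systemic compound:
#' a single-peak pulse `A * (t/tau) * exp(1 - t/tau)` (rise to a maximum
#' near `tau` days, then first-order decline) damped by a growth-dilution
#' term `exp(-g * t)`. Two interpretable parameters reproduce the
#' rise-then-decline residue pattern seen in xylem sap and tissues.
#'
#' @param t Days after treatment (vector).
#' @param amplitude Peak scale `A` (concentration units).
#' @param tau Time-to-peak parameter in days (the undamped maximum is at
#'   `t = tau`).
#' @param growthDilution First-order growth-dilution rate per day.
#' @return Concentration at `t`, same units as `amplitude`.
#' @export
kineticProfile <- function(t, amplitude, tau, growthDilution = 0) {
  stopifnot(amplitude >= 0, tau > 0, growthDilution >= 0)
  amplitude * (t / tau) * exp(1 - t / tau) * exp(-growthDilution * t)
}

#' Default synthetic-study configuration
#'
#' Parameters of the synthetic greenhouse study generated by
#' [simulateStudy()]. The defaults emulate a soil-drench residue study on
#' tomato: control and treated groups of `nReplicates` plants; five sample
#' matrices with rise-then-decline parent kinetics ([kineticProfile()])
#' peaking early in xylem sap and later in tissues; metabolite signal
#' fractions growing as a power of time and staying below 10 percent of
#' parent through 28 days after treatment; per-matrix internal-standard
#' recoveries of 92.6 / 81.0 / 105.7 / 74.1 / 63.2 percent (young leaves,
#' mature leaves, flowers, green fruits, red fruits) with their replicate
#' spreads; matrix-interference features common to both groups; and an
#' instrument noise model (sample-level recovery variation, per-peak
#' lognormal noise at the few-percent repeatability of QC injections,
#' 1 ppm m/z jitter).
#'
#' @param nReplicates Plants per group and sampling interval (default 5).
#' @param tissues Subset of tissue names to simulate (default all five).
#' @param peakRsd Per-peak lognormal relative standard deviation
#'   (default 0.05).
#' @param biologicalRsd Between-plant relative standard deviation of the
#'   true concentration (default 0.2).
#' @param mzJitterPpm Gaussian m/z jitter in ppm (default 1).
#' @param rtJitterMin Gaussian retention-time jitter in minutes
#'   (default 0.02).
#' @param matrixFeatureCount Matrix-interference features per tissue,
#'   planted identically in control and treated samples (default 50).
#' @param responseSlope Detector response per ng/mL of extract
#'   concentration (default 3e4).
#' @param noiseMedian Median baseline noise intensity used for
#'   signal-to-noise (default 200).
#' @return A configuration list consumed by [simulateStudy()].
#' @export
studyConfig <- function(nReplicates = 5,
                        tissues = c("xylem_sap", "young_leaves",
                                    "mature_leaves", "flowers", "fruits"),
                        peakRsd = 0.05, biologicalRsd = 0.2,
                        mzJitterPpm = 1, rtJitterMin = 0.02,
                        matrixFeatureCount = 50, responseSlope = 3e4,
                        noiseMedian = 200) {
  leafDats <- c(7, 14, 21, 28, 35, 42, 49, 56, 77, 84)
  allTissues <- list(
    xylem_sap = list(amplitude = 42, tau = 10, growthDilution = 0.005,
                     dats = leafDats, sampleMass = 1, extractVolume = 1,
                     concentrationFactor = 1, recoveryMean = 100,
                     recoverySd = 0, isNominal = 0),
    young_leaves = list(amplitude = 420, tau = 21, growthDilution = 0.003,
                        dats = leafDats, sampleMass = 0.5, extractVolume = 3,
                        concentrationFactor = 1, recoveryMean = 92.6,
                        recoverySd = 8.3, isNominal = 120),
    mature_leaves = list(amplitude = 1610, tau = 28, growthDilution = 0.004,
                         dats = leafDats, sampleMass = 0.5,
                         extractVolume = 3, concentrationFactor = 1,
                         recoveryMean = 81.0, recoverySd = 9.9,
                         isNominal = 120),
    flowers = list(amplitude = 590, tau = 21, growthDilution = 0.01,
                   dats = c(14, 21, 28, 35, 42, 49), sampleMass = 0.5,
                   extractVolume = 3, concentrationFactor = 5,
                   recoveryMean = 105.7, recoverySd = 8.5, isNominal = 120),
    fruits = list(amplitude = 5.5, tau = 42, growthDilution = 0.01,
                  dats = c(42, 49, 56, 77, 84), sampleMass = 5,
                  extractVolume = 10, concentrationFactor = 10,
                  recoveryMean = 74.1, recoverySd = 17.1,
                  recoveryMeanLate = 63.2, recoverySdLate = 14.5,
                  lateDat = 63, isNominal = 4))
  stopifnot(all(tissues %in% names(allTissues)))
  ## signal fraction relative to parent reached at 84 DAT, per metabolite;
  ## frac(t) = fraction84 * (t / 84)^fractionExponent keeps every M/P ratio
  ## below 10% of parent through 28 DAT
  fractions <- c(
    "IN-J9Z38" = 0.25, "IN-MLA84" = 0.30, "TP619" = 0.18,
    "IN-DBC80" = 0.10, "IN-RNU71" = 0.03, "TP363" = 0.02, "TP423" = 0.02,
    "TP315" = 0.02, "IN-JCZ38" = 0.021, "IN-JSE76" = 0.006,
    "IN-MYX98" = 0.005, "TP633" = 0.034, "TP651a" = 0.02, "TP651b" = 0.01,
    "TP654" = 0.005, "IN-HGW87" = 0.01, "TP405" = 0.01, "TP441" = 0.01,
    "IN-M2G98" = 0.005, "TP316" = 0.005, "TP577" = 0.005)
  list(nReplicates = nReplicates, tissues = allTissues[tissues],
       fractions = fractions, fractionExponent = 2,
       peakRsd = peakRsd, biologicalRsd = biologicalRsd,
       clusterAbundanceRsd = 0.02, mzJitterPpm = mzJitterPpm,
       rtJitterMin = rtJitterMin, matrixFeatureCount = matrixFeatureCount,
       responseSlope = responseSlope, noiseMedian = noiseMedian,
       calibrationLevels = c(0.8, 2, 8, 20, 80, 200, 800),
       calibrationRsd = 0.02, clusterMinRel = 1)
}

## lognormal multiplicative noise with unit mean and given RSD
.lnoise <- function(n, rsd) {
  if (rsd <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + rsd^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

## pattern cache: isotopologue clusters per formula, >= minRel % of base
.cachedClusters <- function(formula, minRel) {
  key <- paste0(formula, "|", minRel)
  cache <- .haloscreen_env$patterns
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .haloscreen_env$patterns <- cache
  }
  if (is.null(cache[[key]])) {
    cl <- clusters(isotopologuePattern(formula, prune = minRel))
    cache[[key]] <- cl
  }
  cache[[key]]
}

.recoveryFor <- function(tis, dat) {
  if (!is.null(tis$lateDat) && dat >= tis$lateDat)
    c(mean = tis$recoveryMeanLate, sd = tis$recoverySdLate)
  else c(mean = tis$recoveryMean, sd = tis$recoverySd)
}

#' Simulate a ground-truthed greenhouse residue study
#'
#' Generates control and treated sample sets with the statistical
#' structure the screening and quantification workflow assumes: treated
#' samples carry the parent compound (concentration following the
#' configured [kineticProfile()] per tissue, with between-plant lognormal
#' variation) and its metabolites (areas equal to the parent area times a
#' time-growing formation fraction), every compound appearing as its full
#' Cl/Br isotope cluster with m/z and abundance jitter; both groups carry
#' the same tissue-specific matrix-interference features; and each sample
#' receives a per-sample internal-standard recovery drawn around its
#' matrix mean, applied multiplicatively to all analyte and
#' internal-standard areas (so that recovery correction can invert it).
#' All randomness is fixed by `seed`; identical inputs give bit-identical
#' output.
#'
#' @param config Configuration list from [studyConfig()].
#' @param seed Integer seed.
#' @param metaboliteTable Compound table supplying formulas and retention
#'   times (default the packaged table).
#' @return A [SyntheticStudy-class] object.
#' @export
simulateStudy <- function(config = studyConfig(), seed = 1,
                          metaboliteTable = loadMetaboliteTable()) {
  seed <- as.integer(seed)
  set.seed(seed)
  tab <- metaboliteTable
  parentName <- tab$name[tab$phase == "parent"]
  mets <- names(config$fractions)
  stopifnot(all(mets %in% tab$name))
  mzOf <- stats::setNames(vapply(tab$formula, cationMz, numeric(1)), tab$name)
  rtOf <- stats::setNames(tab$rt_min, tab$name)
  formulaOf <- stats::setNames(tab$formula, tab$name)

  samples <- list(); features <- list(); truths <- list()
  for (tn in names(config$tissues)) {
    tis <- config$tissues[[tn]]
    ## matrix-interference features, identical in both groups
    nm <- config$matrixFeatureCount
    matrixFeat <- data.frame(
      compound = sprintf("matrix_%s_%02d", tn, seq_len(nm)),
      mz = stats::runif(nm, 150, 1200), rt = stats::runif(nm, 1, 12),
      baseArea = 10^stats::runif(nm, 4.5, 6.5))
    for (dat in tis$dats) {
      for (grp in c("control", "treated")) {
        for (rep in seq_len(config$nReplicates)) {
          sid <- sprintf("%s_%s_d%02d_r%d", substr(grp, 1, 1), tn, dat, rep)
          rec <- .recoveryFor(tis, dat)
          recovery <- max(20, stats::rnorm(1, rec["mean"], rec["sd"]))
          recMeasured <- recovery * .lnoise(1, config$peakRsd)
          samples[[length(samples) + 1L]] <- data.frame(
            sample_id = sid, group = grp, tissue = tn, dat = dat,
            replicate = rep,
            concentration_factor = tis$concentrationFactor,
            sample_mass = tis$sampleMass,
            extract_volume = tis$extractVolume,
            recovery_applied_pct = recovery,
            recovery_measured_pct = recMeasured,
            stringsAsFactors = FALSE)
          sampleFeats <- list()
          if (grp == "treated") {
            concFw <- kineticProfile(dat, tis$amplitude, tis$tau,
                                     tis$growthDilution) *
              .lnoise(1, config$biologicalRsd)
            extractConc <- concFw * tis$sampleMass *
              tis$concentrationFactor / tis$extractVolume
            parentBase <- extractConc * (recovery / 100) *
              config$responseSlope
            frac <- config$fractions *
              (dat / 84)^config$fractionExponent
            cmpds <- c(parentName, mets)
            fracs <- c(1, unname(frac))
            for (k in seq_along(cmpds)) {
              nmK <- cmpds[k]
              area <- parentBase * fracs[k] * .lnoise(1, config$peakRsd)
              cl <- .cachedClusters(formulaOf[[nmK]], config$clusterMinRel)
              obsCl <- data.frame(
                mz = cl$mz * (1 + stats::rnorm(nrow(cl), 0,
                                               config$mzJitterPpm * 1e-6)),
                abundance = cl$abundance *
                  .lnoise(nrow(cl), config$clusterAbundanceRsd))
              sampleFeats[[length(sampleFeats) + 1L]] <- data.frame(
                sample_id = sid,
                mz = mzOf[[nmK]] * (1 + stats::rnorm(1, 0,
                                      config$mzJitterPpm * 1e-6)),
                rt = rtOf[[nmK]] + stats::rnorm(1, 0, config$rtJitterMin),
                area = area,
                snr = area / (config$noiseMedian * .lnoise(1, 0.2)),
                compound = nmK, stringsAsFactors = FALSE)
              sampleFeats[[length(sampleFeats)]]$cluster <- I(list(obsCl))
              truths[[length(truths) + 1L]] <- data.frame(
                sample_id = sid, compound = nmK,
                true_conc_fw = if (nmK == parentName) concFw else NA_real_,
                true_area = parentBase * fracs[k],
                recovery_pct = recovery, mp_fraction = fracs[k],
                stringsAsFactors = FALSE)
            }
          }
          ## matrix features (both groups): C-only style A+1 companion
          for (k in seq_len(nrow(matrixFeat))) {
            area <- matrixFeat$baseArea[k] * .lnoise(1, config$peakRsd)
            mzk <- matrixFeat$mz[k] *
              (1 + stats::rnorm(1, 0, config$mzJitterPpm * 1e-6))
            obsCl <- data.frame(mz = c(mzk, mzk + 1.00336),
                                abundance = c(100, 15))
            sampleFeats[[length(sampleFeats) + 1L]] <- data.frame(
              sample_id = sid, mz = mzk,
              rt = matrixFeat$rt[k] +
                stats::rnorm(1, 0, config$rtJitterMin),
              area = area,
              snr = area / (config$noiseMedian * .lnoise(1, 0.2)),
              compound = matrixFeat$compound[k], stringsAsFactors = FALSE)
            sampleFeats[[length(sampleFeats)]]$cluster <- I(list(obsCl))
          }
          features[[length(features) + 1L]] <-
            do.call(rbind, sampleFeats)
        }
      }
    }
  }
  new("SyntheticStudy",
      samples = do.call(rbind, samples),
      features = do.call(rbind, features),
      truth = do.call(rbind, truths),
      config = config, seed = seed)
}

#' Render raw-style spectra for one simulated sample
#'
#' Converts one sample of a [SyntheticStudy-class] into the raw formats
#' the ingestion side of the pipeline consumes: centroided MS1 peak
#' frames (each feature's isotope cluster at its apex retention time,
#' flanked by two lower-intensity frames, plus uniform baseline noise
#' peaks over the 150-1200 m/z scan range) and MS2 spectra containing the
#' planted characteristic fragments of each treated compound.
#'
#' @param study A [SyntheticStudy-class] object.
#' @param sampleId Sample to render.
#' @param noisePeaksPerFrame Baseline noise peaks added per frame
#'   (default 150).
#' @param frameSpacing Retention-time spacing of the flanking frames in
#'   minutes (default 0.05).
#' @return List with `frames` (data.frame `rt`, `mz`, `intensity`) and
#'   `ms2` (list of spectra in the [readMgf()] structure).
#' @export
renderSpectra <- function(study, sampleId, noisePeaksPerFrame = 150,
                          frameSpacing = 0.05) {
  feats <- studyFeatures(study)
  feats <- feats[feats$sample_id == sampleId, , drop = FALSE]
  if (nrow(feats) == 0L) stop("unknown sample: ", sampleId)
  cfg <- studyConfigUsed(study)
  frames <- list()
  for (i in seq_len(nrow(feats))) {
    cl <- feats$cluster[[i]]
    ints <- feats$area[i] * cl$abundance / 100
    for (off in c(-frameSpacing, 0, frameSpacing)) {
      scale <- if (off == 0) 1 else 0.6
      frames[[length(frames) + 1L]] <- data.frame(
        rt = feats$rt[i] + off, mz = cl$mz, intensity = ints * scale)
    }
  }
  rts <- sort(unique(round(feats$rt, 3)))
  for (rt in rts) {
    frames[[length(frames) + 1L]] <- data.frame(
      rt = rt, mz = stats::runif(noisePeaksPerFrame, 150, 1200),
      intensity = stats::rexp(noisePeaksPerFrame, 1 / cfg$noiseMedian))
  }
  frames <- do.call(rbind, frames)
  frames <- frames[order(frames$rt, frames$mz), ]
  rownames(frames) <- NULL
  ## MS2 for planted (non-matrix) compounds with known fragments
  tabl <- loadMetaboliteTable()
  ms2 <- list()
  planted <- feats[feats$compound %in% tabl$name, , drop = FALSE]
  for (i in seq_len(nrow(planted))) {
    fr <- tabl$fragment_ions[[match(planted$compound[i], tabl$name)]]
    if (!length(fr)) next
    ms2[[length(ms2) + 1L]] <- list(
      title = paste0(planted$compound[i], "|", sampleId),
      precursor_mz = planted$mz[i],
      rt_seconds = planted$rt[i] * 60,
      peaks = data.frame(mz = fr,
                         intensity = planted$area[i] *
                           stats::runif(length(fr), 0.05, 0.4)))
  }
  list(frames = frames, ms2 = ms2)
}
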