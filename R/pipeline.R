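#' @include screen.R simulate.R quant.R report.R
NULL

#' Screen a simulated study end to end
#'
#' Runs the full feature-level screening chain on every treated sample of
#' a [SyntheticStudy-class]: control-signal elimination against the pooled
#' control features of the same tissue, intensity and signal-to-noise
#' thresholds, the Cl/Br isotope filter, and suspect matching. Results
#' keep the simulator's hidden truth label so detection and false-positive
#' rates can be measured against the ground truth.
#'
#' @param study A [SyntheticStudy-class] object.
#' @param suspects Suspect list (default [suspectList()]).
#' @param mzTolPpm,rtTol Matching tolerances for control elimination and
#'   suspect matching (defaults 5 ppm, 0.1 min).
#' @param minArea,minSnr Screening thresholds (defaults 1e4 and 10).
#' @return data.frame of suspect hits: one row per (treated sample,
#'   feature, suspect) with sample metadata columns merged in; the hidden
#'   `compound` column carries the simulator truth.
#' @export
screenStudy <- function(study, suspects = suspectList(), mzTolPpm = 5,
                        rtTol = 0.1, minArea = 1e4, minSnr = 10) {
  samp <- studySamples(study)
  feats <- studyFeatures(study)
  hits <- list()
  for (tn in unique(samp$tissue)) {
    ctrlIds <- samp$sample_id[samp$tissue == tn & samp$group == "control"]
    trtIds <- samp$sample_id[samp$tissue == tn & samp$group == "treated"]
    ctrlPool <- feats[feats$sample_id %in% ctrlIds, , drop = FALSE]
    for (sid in trtIds) {
      f <- feats[feats$sample_id == sid, , drop = FALSE]
      f <- subtractControl(f, ctrlPool, mzTolPpm = mzTolPpm, rtTol = rtTol)
      f <- applyThresholds(f, minArea = minArea, minSnr = minSnr)
      f <- halogenFilter(f)
      h <- matchSuspects(f, suspects, mzTolPpm = mzTolPpm, rtTol = rtTol)
      if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits)) return(data.frame())
  hits <- do.call(rbind, hits)
  out <- merge(hits, samp, by = "sample_id", sort = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a calibration standard series
#'
#' Detector responses for the configured working-standard concentrations
#' under the configured response slope and relative calibration noise.
#'
#' @param config Study configuration from [studyConfig()].
#' @return data.frame with `concentration` (ng/mL) and `response`.
#' @export
simulateCalibration <- function(config = studyConfig()) {
  conc <- config$calibrationLevels
  resp <- config$responseSlope * conc *
    (1 + stats::rnorm(length(conc), 0, config$calibrationRsd))
  data.frame(concentration = conc, response = resp)
}

#' Quantify the parent compound in screened samples
#'
#' Completes the quantification chain for parent-compound hits: inverse
#' prediction of the extract concentration from the calibration curve,
#' conversion to a fresh-weight basis from the sample mass, extract
#' volume and concentration factor, and per-sample recovery correction by
#' the measured internal-standard recovery. Ground-truth concentrations
#' are joined in for accuracy assessment.
#'
#' @param study A [SyntheticStudy-class] object.
#' @param hits Hit table from [screenStudy()].
#' @param curve A [CalibrationCurve-class] object.
#' @param parent Parent compound name (default `"Cyantraniliprole"`).
#' @return data.frame with one row per quantified sample: `sample_id`,
#'   `tissue`, `dat`, `replicate`, `conc_extract`, `conc_fw`,
#'   `conc_fw_corrected`, `recovery_pct`, `true_conc_fw`, `in_range`.
#' @export
quantifyParent <- function(study, hits, curve, parent = "Cyantraniliprole") {
  ph <- hits[hits$name == parent, , drop = FALSE]
  if (nrow(ph) == 0L) return(data.frame())
  pred <- predictConcentration(curve, ph$area)
  fw <- concentrationFW(pred$concentration, ph$sample_mass,
                        ph$extract_volume, ph$concentration_factor)
  corrected <- correctConcentration(fw, ph$recovery_measured_pct)
  tr <- groundTruth(study)
  tr <- tr[tr$compound == parent, c("sample_id", "true_conc_fw")]
  out <- data.frame(sample_id = ph$sample_id, tissue = ph$tissue,
                    dat = ph$dat, replicate = ph$replicate,
                    conc_extract = pred$concentration, conc_fw = fw,
                    conc_fw_corrected = corrected,
                    recovery_pct = ph$recovery_measured_pct,
                    in_range = pred$in_range, stringsAsFactors = FALSE)
  merge(out, tr, by = "sample_id", sort = FALSE)
}

#' Convert screening hits to a tidy study table
#'
#' @param hits Hit table from [screenStudy()].
#' @return Tidy study table (`compound`, `tissue`, `dat`, `replicate`,
#'   `area`) for [mpRatios()] and [summarizeTimeseries()]; when a feature
#'   matched several suspects, each match contributes its own row.
#' @export
studyTableFromHits <- function(hits) {
  data.frame(compound = hits$name, tissue = hits$tissue, dat = hits$dat,
             replicate = hits$replicate, area = hits$area,
             stringsAsFactors = FALSE)
}
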