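#' @import methods
NULL

#' ElementalFormula: an element-count map
#'
#' The unit of all mass arithmetic in the package: a map from element symbol
#' (restricted to C, H, N, O, S, Cl, Br) to a non-negative atom count. Create
#' with [parseFormula()] or [newFormula()].
#'
#' @slot counts Named integer vector of atom counts; names are element
#'   symbols from [supportedElements()], all counts non-negative, at least
#'   one atom in total.
#' @seealso [monoisotopicMass()], [cationMz()], [rdbe()], [nitrogenRuleOk()]
#' @export
setClass("ElementalFormula", representation(counts = "integer"))

setValidity("ElementalFormula", function(object) {
  cnt <- object@counts
  if (is.null(names(cnt)) || !all(names(cnt) %in% supportedElements()))
    return("element symbols must be from supportedElements()")
  if (anyNA(cnt) || any(cnt < 0L))
    return("atom counts must be non-negative integers")
  if (sum(cnt) < 1L)
    return("a formula must contain at least one atom")
  if (anyDuplicated(names(cnt)))
    return("duplicated element symbols")
  TRUE
})

#' IsotopePattern: binned isotopologue clusters of an ion
#'
#' An ordered set of isotopologue clusters for one ion species, as produced
#' by [isotopologuePattern()]. Isotopologues falling within `binWidth` Da of
#' each other are merged into clusters; cluster abundances are normalized so
#' the base (most abundant) cluster is 100.
#'
#' @slot clusters data.frame with columns `mz` (abundance-weighted centroid
#'   m/z, Da), `abundance` (percent of base peak), `species_mz` (m/z of the
#'   single most abundant isotopologue in the cluster) and `nominal_shift`
#'   (integer nominal-mass offset from the monoisotopic cluster). Sorted by
#'   ascending `mz`.
#' @slot binWidth Aggregation bin in Da.
#' @slot pruneRel Relative-abundance pruning threshold (percent of base)
#'   applied to the clusters.
#' @slot rawTotal Total isotopologue probability before normalization
#'   (equals 1 up to pruning loss; kept for conservation checks).
#' @export
setClass("IsotopePattern",
         representation(clusters = "data.frame", binWidth = "numeric",
                        pruneRel = "numeric", rawTotal = "numeric"))

setValidity("IsotopePattern", function(object) {
  cl <- object@clusters
  need <- c("mz", "abundance", "species_mz", "nominal_shift")
  if (!all(need %in% names(cl)))
    return(paste("clusters must have columns", paste(need, collapse = ", ")))
  if (nrow(cl) == 0L) return("pattern must contain at least one cluster")
  if (is.unsorted(cl$mz, strictly = TRUE))
    return("clusters must be sorted by strictly increasing m/z")
  if (abs(max(cl$abundance) - 100) > 1e-9)
    return("base cluster abundance must be 100")
  if (any(cl$abundance <= 0)) return("abundances must be positive")
  TRUE
})

#' CalibrationCurve: a fitted external-calibration line
#'
#' Least-squares calibration of detector response against nominal
#' concentration, fitted by [fitCalibration()] and inverted by
#' [predictConcentration()].
#'
#' @slot slope,intercept Fitted line coefficients (response per ng/mL, and
#'   response at zero).
#' @slot rSquared Coefficient of determination of the fit.
#' @slot range Fitted concentration range (ng/mL); inverse predictions
#'   outside it are flagged.
#' @slot levels data.frame of the calibration points (`concentration`,
#'   `response`).
#' @slot weighting `"none"` or `"1/x"`.
#' @export
setClass("CalibrationCurve",
         representation(slope = "numeric", intercept = "numeric",
                        rSquared = "numeric", range = "numeric",
                        levels = "data.frame", weighting = "character"))

setValidity("CalibrationCurve", function(object) {
  if (length(object@range) != 2L || object@range[1] >= object@range[2])
    return("range must be (low, high) with low < high")
  if (nrow(object@levels) < 5L)
    return("a calibration needs at least 5 levels")
  TRUE
})

#' LodResult: Student-t based detection limits
#'
#' Result of [computeLod()]: the method limit of detection from replicate
#' spiked analyses, LOD = t * S_s with t the one-tailed (1 - alpha) Student
#' quantile at n - 1 degrees of freedom, and LOQ = 3.3 * LOD.
#'
#' @slot matrix Label of the sample matrix the replicates came from.
#' @slot nInjections Number of replicate injections.
#' @slot tCritical One-tailed Student-t critical value at `nInjections - 1`
#'   degrees of freedom.
#' @slot ss Standard deviation of the replicate spiked results.
#' @slot lod,loq Detection and quantification limits, in the units of the
#'   replicate results.
#' @export
setClass("LodResult",
         representation(matrix = "character", nInjections = "integer",
                        tCritical = "numeric", ss = "numeric",
                        lod = "numeric", loq = "numeric"))

setValidity("LodResult", function(object) {
  if (object@nInjections < 3L) return("need at least 3 replicate injections")
  if (object@ss < 0) return("standard deviation must be non-negative")
  if (abs(object@lod - object@tCritical * object@ss) > 1e-9 * max(1, object@lod))
    return("lod must equal tCritical * ss")
  if (abs(object@loq - 3.3 * object@lod) > 1e-9 * max(1, object@loq))
    return("loq must equal 3.3 * lod")
  TRUE
})

#' SyntheticStudy: a ground-truthed simulated greenhouse study
#'
#' Output of [simulateStudy()]: per-sample metadata, a feature table of the
#' kind the screening workflow consumes, and the generating ground truth.
#'
#' @slot samples data.frame of sample metadata (`sample_id`, `group`,
#'   `tissue`, `dat`, `replicate`, `concentration_factor`).
#' @slot features data.frame of MS1 features (`sample_id`, `mz`, `rt`,
#'   `area`, `snr`, `compound` hidden truth label, list-column `cluster` of
#'   observed isotope clusters).
#' @slot truth data.frame of per-sample, per-compound ground truth
#'   (`sample_id`, `compound`, `true_conc_fw`, `true_area`, `recovery_pct`,
#'   `mp_fraction`).
#' @slot config The study configuration list used (see [studyConfig()]).
#' @slot seed Integer seed that fixes all randomness.
#' @export
setClass("SyntheticStudy",
         representation(samples = "data.frame", features = "data.frame",
                        truth = "data.frame", config = "list",
                        seed = "integer"))

setValidity("SyntheticStudy", function(object) {
  if (!all(c("sample_id", "group", "tissue", "dat", "replicate") %in%
           names(object@samples)))
    return("samples is missing required metadata columns")
  if (!all(object@features$sample_id %in% object@samples$sample_id))
    return("features reference unknown samples")
  TRUE
})
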