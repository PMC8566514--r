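#' @include AllClasses.R AllGenerics.R
NULL

#' Fit an external calibration curve
#'
#' Ordinary (or 1/x-weighted) least-squares line of detector response
#' against nominal standard concentration.
#'
#' @param concentration Nominal standard concentrations (ng/mL), at least
#'   five distinct levels.
#' @param response Measured responses (peak areas), same length.
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return A [CalibrationCurve-class] object.
#' @export
fitCalibration <- function(concentration, response,
                           weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  stopifnot(length(concentration) == length(response))
  if (length(unique(concentration)) < 5L)
    stop("calibration requires at least 5 distinct concentration levels")
  w <- if (weighting == "1/x") 1 / concentration else rep(1, length(response))
  fit <- stats::lm(response ~ concentration, weights = w)
  ## r^2 computed directly: summary.lm warns on noise-free synthetic fits
  rsq <- 1 - sum(w * stats::residuals(fit)^2) /
    sum(w * (response - stats::weighted.mean(response, w))^2)
  new("CalibrationCurve",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      rSquared = rsq,
      range = range(concentration),
      levels = data.frame(concentration = concentration,
                          response = response),
      weighting = weighting)
}

#' Inverse-predict concentrations from a calibration curve
#'
#' @param curve A [CalibrationCurve-class] object.
#' @param response Numeric vector of measured responses.
#' @return data.frame with `concentration` (ng/mL) and `in_range` (logical;
#'   `FALSE` flags extrapolation beyond the fitted standards).
#' @export
predictConcentration <- function(curve, response) {
  conc <- (response - intercept(curve)) / slope(curve)
  rng <- calibrationRange(curve)
  data.frame(concentration = conc,
             in_range = conc >= rng[1] & conc <= rng[2])
}

#' Recovery-correct a measured concentration
#'
#' Per-sample correction by the internal-standard recovery: the measured
#' value is multiplied by `100 / recovery_pct`, exactly inverting the
#' proportional matrix loss the recovery quantifies.
#'
#' @param measured Measured concentration(s).
#' @param recoveryPct Recovery percentage(s), strictly positive.
#' @return Corrected concentration(s), `measured * 100 / recoveryPct`.
#' @examples
#' correctConcentration(50, 50)  # 100
#' @export
correctConcentration <- function(measured, recoveryPct) {
  if (any(recoveryPct <= 0)) stop("recovery must be positive")
  measured * 100 / recoveryPct
}

#' Student-t based limit of detection
#'
#' Method LOD from replicate analyses of a low-level spiked sample:
#' `LOD = t * S_s`, with `t` the one-tailed `(1 - alpha)` Student quantile
#' at `n - 1` degrees of freedom (computed, not table-looked-up; 3.143 for
#' seven injections at the 99th percentile) and `S_s` the sample standard
#' deviation of the replicate results. `LOQ = 3.3 * LOD`.
#'
#' @param spikedResults Numeric vector of replicate spiked-sample results
#'   (length >= 3).
#' @param alpha One-tailed significance level (default 0.01).
#' @param matrix Optional label of the sample matrix.
#' @return A [LodResult-class] object. Zero replicate variance yields
#'   `LOD = 0` with a warning.
#' @examples
#' lod(computeLod(c(2.1, 1.9, 2.0, 2.2, 1.8, 2.1, 1.9)))
#' @export
computeLod <- function(spikedResults, alpha = 0.01, matrix = "unspecified") {
  n <- length(spikedResults)
  if (n < 3L) stop("need at least 3 replicate spiked results")
  ss <- stats::sd(spikedResults)
  if (ss == 0) warning("zero variance among replicates; LOD is 0")
  tcrit <- stats::qt(1 - alpha, df = n - 1)
  lodVal <- tcrit * ss
  new("LodResult", matrix = matrix, nInjections = as.integer(n),
      tCritical = tcrit, ss = ss, lod = lodVal, loq = 3.3 * lodVal)
}

#' Convert an extract concentration to a fresh-weight basis
#'
#' @param extractConc Concentration in the final extract (ng/mL).
#' @param sampleMass Fresh sample mass extracted (g).
#' @param extractVolume Extraction solvent volume (mL).
#' @param concentrationFactor Fold-concentration applied to the extract
#'   before injection (default 1; e.g. 5 for blown-down flower extracts).
#' @return Tissue concentration in ng/g fresh weight:
#'   `extractConc * extractVolume / (sampleMass * concentrationFactor)`.
#' @examples
#' concentrationFW(10, 0.5, 3.0)  # 60 ng/g
#' @export
concentrationFW <- function(extractConc, sampleMass, extractVolume,
                            concentrationFactor = 1) {
  if (any(sampleMass <= 0) || any(extractVolume <= 0) ||
      any(concentrationFactor <= 0))
    stop("sample mass, extract volume and concentration factor must be > 0")
  extractConc * extractVolume / (sampleMass * concentrationFactor)
}
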