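#' @include AllClasses.R
NULL

#' Accessors for haloscreen S4 objects
#'
#' Small accessor generics for the package's S4 containers; prefer these to
#' direct slot access.
#'
#' @param object An object of the documented class.
#' @return The slot value described for each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("elementCounts", function(object) standardGeneric("elementCounts"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))

#' @rdname accessors
#' @export
setGeneric("slope", function(object) standardGeneric("slope"))

#' @rdname accessors
#' @export
setGeneric("intercept", function(object) standardGeneric("intercept"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("calibrationRange",
           function(object) standardGeneric("calibrationRange"))

#' @rdname accessors
#' @export
setGeneric("lod", function(object) standardGeneric("lod"))

#' @rdname accessors
#' @export
setGeneric("loq", function(object) standardGeneric("loq"))

#' @rdname accessors
#' @export
setGeneric("tCritical", function(object) standardGeneric("tCritical"))

#' @rdname accessors
#' @export
setGeneric("studySamples", function(object) standardGeneric("studySamples"))

#' @rdname accessors
#' @export
setGeneric("studyFeatures", function(object) standardGeneric("studyFeatures"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("studyConfigUsed",
           function(object) standardGeneric("studyConfigUsed"))

## ---- methods -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("elementCounts", "ElementalFormula", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("clusters", "IsotopePattern", function(object) object@clusters)

#' @rdname accessors
#' @export
setMethod("binWidth", "IsotopePattern", function(object) object@binWidth)

#' @rdname accessors
#' @export
setMethod("slope", "CalibrationCurve", function(object) object@slope)

#' @rdname accessors
#' @export
setMethod("intercept", "CalibrationCurve", function(object) object@intercept)

#' @rdname accessors
#' @export
setMethod("rSquared", "CalibrationCurve", function(object) object@rSquared)

#' @rdname accessors
#' @export
setMethod("calibrationRange", "CalibrationCurve",
          function(object) object@range)

#' @rdname accessors
#' @export
setMethod("lod", "LodResult", function(object) object@lod)

#' @rdname accessors
#' @export
setMethod("loq", "LodResult", function(object) object@loq)

#' @rdname accessors
#' @export
setMethod("tCritical", "LodResult", function(object) object@tCritical)

#' @rdname accessors
#' @export
setMethod("studySamples", "SyntheticStudy", function(object) object@samples)

#' @rdname accessors
#' @export
setMethod("studyFeatures", "SyntheticStudy", function(object) object@features)

#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticStudy", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("studyConfigUsed", "SyntheticStudy", function(object) object@config)

## ---- show ----------------------------------------------------------------

setMethod("show", "ElementalFormula", function(object) {
  cat("ElementalFormula:", formatFormula(object),
      sprintf("(monoisotopic %.4f Da)\n", monoisotopicMass(object)))
})

setMethod("show", "IsotopePattern", function(object) {
  cl <- object@clusters
  cat(sprintf("IsotopePattern: %d clusters (bin %.3g Da, prune %.3g%%)\n",
              nrow(cl), object@binWidth, object@pruneRel))
  print(data.frame(mz = round(cl$mz, 4),
                   abundance = round(cl$abundance, 2),
                   shift = cl$nominal_shift), row.names = FALSE)
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve: response = %.6g * conc %+.6g (r^2 = %.5f)\n",
    object@slope, object@intercept, object@rSquared))
  cat(sprintf("  %d levels over %.3g-%.3g ng/mL, weighting: %s\n",
              nrow(object@levels), object@range[1], object@range[2],
              object@weighting))
})

setMethod("show", "LodResult", function(object) {
  cat(sprintf(
    "LodResult [%s]: n = %d, t = %.3f, S_s = %.4g -> LOD %.4g, LOQ %.4g\n",
    object@matrix, object@nInjections, object@tCritical, object@ss,
    object@lod, object@loq))
})

setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf(
    "SyntheticStudy (seed %d): %d samples, %d features, %d truth rows\n",
    object@seed, nrow(object@samples), nrow(object@features),
    nrow(object@truth)))
  print(table(object@samples$group, object@samples$tissue))
})
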