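#' @include chem.R
NULL

#' Match MS2 fragment peaks against a fragment rule set
#'
#' Confirms a candidate structure by its MS2 spectrum using transparent,
#' data-driven rules of two kinds: characteristic ions (a fragment expected
#' at a fixed m/z) and neutral losses (a fragment expected at precursor m/z
#' minus a fixed neutral mass, e.g. the anhydroglucose loss of 162.0528 Da
#' diagnostic of glycosides). Unmatched spectrum peaks are reported
#' alongside the matches, never silently dropped.
#'
#' @param fragmentMz Numeric vector of observed MS2 fragment m/z values
#'   (may be empty: an empty spectrum yields an empty match).
#' @param precursorMz Observed precursor m/z of the spectrum.
#' @param rules data.frame of fragment rules with columns `kind`
#'   (`"characteristic_ion"` or `"neutral_loss"`), `mz_or_mass` (Da) and
#'   `label`; see [loadFragmentRules()].
#' @param mzTolPpm Fragment matching tolerance in ppm (default 10).
#' @param candidateMz Optional candidate `[M+H]+` m/z; when given, the
#'   precursor must agree with it within `precursorTolPpm` or an error is
#'   raised.
#' @param precursorTolPpm Precursor gate in ppm (default 25, the isolation
#'   tolerance of a targeted inclusion list).
#' @return A list with `matches` (data.frame: `observed_mz`, `kind`,
#'   `label`, `expected_mz`, `ppm`) and `unmatched` (numeric vector of
#'   unexplained peaks).
#' @export
matchFragments <- function(fragmentMz, precursorMz, rules, mzTolPpm = 10,
                           candidateMz = NULL, precursorTolPpm = 25) {
  stopifnot(all(c("kind", "mz_or_mass", "label") %in% names(rules)),
            all(rules$mz_or_mass > 0))
  if (!is.null(candidateMz) &&
      abs(ppmError(precursorMz, candidateMz)) > precursorTolPpm)
    stop(sprintf("precursor %.4f outside %g ppm of candidate %.4f",
                 precursorMz, precursorTolPpm, candidateMz))
  expected <- ifelse(rules$kind == "neutral_loss",
                     precursorMz - rules$mz_or_mass, rules$mz_or_mass)
  out <- list()
  matched <- logical(length(fragmentMz))
  for (i in seq_along(fragmentMz)) {
    ok <- expected > 0 &
      abs(fragmentMz[i] - expected) <= precursorMz * mzTolPpm * 1e-6
    for (j in which(ok)) {
      matched[i] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        observed_mz = fragmentMz[i], kind = rules$kind[j],
        label = rules$label[j], expected_mz = expected[j],
        ppm = ppmError(fragmentMz[i], expected[j]),
        stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(out)) do.call(rbind, out)
  else data.frame(observed_mz = numeric(0), kind = character(0),
                  label = character(0), expected_mz = numeric(0),
                  ppm = numeric(0), stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  list(matches = matches, unmatched = fragmentMz[!matched])
}

#' Assign an identification confidence level
#'
#' Implements the identification-confidence scheme used for suspect
#' screening without reference standards (Schymanski-style levels). In the
#' convention implemented here: level 1 requires a reference standard
#' (retention time and MS2 confirmed); level 2b requires matched
#' characteristic fragments for a structure previously reported in the
#' literature or registration documents; level 3 covers matched fragments
#' where alternative structures (e.g. conjugation positions) remain
#' possible; and candidates without adequate MS2 fragments fall to level 5
#' (exact mass of interest only). Levels 2a and 4 are representable but not
#' produced by this rule set.
#'
#' @param hasFragments Logical: were characteristic MS2 fragments matched?
#' @param hasReferenceStandard Logical: is an authentic standard available
#'   and confirmed by RT and MS2?
#' @param previouslyReported Logical: has this structure been reported
#'   before (registration documents or literature)?
#' @return Character vector of levels among `"1"`, `"2b"`, `"3"`, `"5"`.
#'   All arguments are vectorized and recycled.
#' @examples
#' assignConfidence(TRUE, TRUE, TRUE)    # "1"
#' assignConfidence(TRUE, FALSE, TRUE)   # "2b"
#' assignConfidence(TRUE, FALSE, FALSE)  # "3"
#' assignConfidence(FALSE, FALSE, TRUE)  # "5"
#' @export
assignConfidence <- function(hasFragments, hasReferenceStandard = FALSE,
                             previouslyReported = FALSE) {
  n <- max(length(hasFragments), length(hasReferenceStandard),
           length(previouslyReported))
  hasFragments <- rep_len(hasFragments, n)
  hasReferenceStandard <- rep_len(hasReferenceStandard, n)
  previouslyReported <- rep_len(previouslyReported, n)
  ifelse(!hasFragments, "5",
         ifelse(hasReferenceStandard, "1",
                ifelse(previouslyReported, "2b", "3")))
}

#' Classify a metabolite into a transformation phase
#'
#' Walks the transformation pathway graph from the parent compound to the
#' suspect and classifies it as: `breakdown` if any edge on the path is a
#' cleavage reaction (carboxamide-bridge cleavage); `phase_II` if the
#' terminal edge is a conjugation (glycosylation, amino-acid conjugation);
#' otherwise `phase_I` (functionalization reactions such as ring closure,
#' demethylation, hydroxylation, dehalogenation). The parent maps to
#' `parent`; a suspect absent from the graph is `unclassified`.
#'
#' @param name Character vector of compound names to classify.
#' @param edges Pathway edge list: data.frame with columns `from`, `to`,
#'   `reaction`, `reaction_class` (one of `"functionalization"`,
#'   `"conjugation"`, `"cleavage"`); see [loadPathwayEdges()].
#' @param parent Name of the parent compound (default
#'   `"Cyantraniliprole"`).
#' @return Character vector in `{parent, phase_I, phase_II, breakdown,
#'   unclassified}`.
#' @export
classifyPhase <- function(name, edges, parent = "Cyantraniliprole") {
  stopifnot(all(c("from", "to", "reaction_class") %in% names(edges)))
  classifyOne <- function(nm) {
    if (nm == parent) return("parent")
    ## walk up: each node has a unique precursor in the curated graph
    path <- character(0)
    cur <- nm
    repeat {
      i <- which(edges$to == cur)
      if (length(i) == 0L)
        return(if (length(path)) "unclassified_orphan" else "unclassified")
      i <- i[1]
      path <- c(edges$reaction_class[i], path)
      cur <- edges$from[i]
      if (cur == parent) break
      if (length(path) > nrow(edges)) stop("pathway graph contains a cycle")
    }
    if (any(path == "cleavage")) return("breakdown")
    if (path[length(path)] == "conjugation") return("phase_II")
    "phase_I"
  }
  out <- vapply(name, classifyOne, character(1), USE.NAMES = FALSE)
  ifelse(out == "unclassified_orphan", "unclassified", out)
}
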