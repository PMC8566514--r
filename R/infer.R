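#' @include chem.R
NULL

#' Element count bounds for formula enumeration
#'
#' Default search-space bounds for [enumerateFormulas()]. The defaults cover
#' every formula in the packaged suspect table with comfortable margins.
#'
#' @param C,H,N,O,S,Cl,Br Integer vectors `c(min, max)` per element.
#' @return A named list of `c(min, max)` integer pairs.
#' @export
elementBounds <- function(C = c(0, 40), H = c(0, 60), N = c(0, 10),
                          O = c(0, 12), S = c(0, 2), Cl = c(0, 2),
                          Br = c(0, 2)) {
  b <- list(C = C, H = H, N = N, O = O, S = S, Cl = Cl, Br = Br)
  for (el in names(b)) {
    v <- as.integer(b[[el]])
    if (length(v) != 2L || anyNA(v) || v[1] < 0L || v[1] > v[2])
      stop("invalid bounds for ", el)
    b[[el]] <- v
  }
  b
}

#' Enumerate candidate molecular formulas for an observed cation m/z
#'
#' Exhaustively enumerates neutral formulas within the element bounds whose
#' `[M+H]+` m/z lies within a ppm tolerance of the observed value, then
#' filters by the nitrogen rule, an RDBE admissibility window of integral
#' values in `[0, 40]` (even-electron neutral molecules) and, optionally,
#' the requirement of at least one Cl or Br atom (the halogen-retention
#' assumption of targeted transformation-product screening). Candidates are
#' ranked by absolute ppm error, then (when an observed isotope pattern is
#' supplied) by isotope-fit score, then by fewer heteroatoms, then by
#' formula string; the ranking is total and deterministic.
#'
#' The search is a residual-mass descent over elements in decreasing mass
#' order with pruning by the attainable mass of the remaining elements; it
#' is exact, not stochastic.
#'
#' @param mz Observed `[M+H]+` m/z (Da).
#' @param tol Mass tolerance in ppm (default 5).
#' @param bounds Element bounds from [elementBounds()].
#' @param requireHalogen Keep only formulas with at least one Cl or Br
#'   (default `TRUE`).
#' @param observedPattern Optional observed [IsotopePattern-class] (or a
#'   data.frame with `mz` and `abundance`) used to compute per-candidate
#'   isotope-fit scores.
#' @param rdbeRange Admissible RDBE interval for the neutral molecule.
#' @return data.frame with columns `rank`, `formula`, `calcd_mz`, `ppm`,
#'   `rdbe`, `isotope_score` (NA when no observed pattern is given), sorted
#'   by rank. Zero rows is a valid outcome.
#' @examples
#' cands <- enumerateFormulas(473.0126)
#' cands[cands$formula == "C19H14BrClN6O2", ]
#' @export
enumerateFormulas <- function(mz, tol = 5, bounds = elementBounds(),
                              requireHalogen = TRUE, observedPattern = NULL,
                              rdbeRange = c(0, 40)) {
  stopifnot(mz > 0, tol > 0)
  mono <- .monoMasses()
  tolDa <- mz * tol * 1e-6
  ## target neutral monoisotopic mass
  target <- mz - (mono[["H"]] - .ELECTRON_MASS)
  heavy <- c("Br", "Cl", "S", "O", "N")  # decreasing mass order
  res <- vector("list", 64L)
  nres <- 0L
  bC <- bounds$C; bH <- bounds$H
  mC <- mono[["C"]]; mH <- mono[["H"]]
  maxTail <- function(i) {
    ## max attainable mass from elements heavy[i..], C and H
    els <- heavy[seq(i, length(heavy))]
    sum(vapply(els, function(e) bounds[[e]][2] * mono[[e]], numeric(1))) +
      bC[2] * mC + bH[2] * mH
  }
  tails <- vapply(seq_along(heavy), maxTail, numeric(1))
  recurse <- function(i, counts, massSoFar) {
    if (massSoFar > target + tolDa) return()
    if (i > length(heavy)) {
      ## vectorize over C; H determined by the residual
      rem0 <- target - massSoFar
      cMax <- min(bC[2], floor((rem0 + tolDa) / mC))
      if (cMax < bC[1]) return()
      cs <- bC[1]:cMax
      rem <- rem0 - cs * mC
      hs <- round(rem / mH)
      ok <- hs >= bH[1] & hs <= bH[2] & abs(rem - hs * mH) <= tolDa
      for (k in which(ok)) {
        cnt <- c(counts, C = cs[k], H = as.integer(hs[k]))
        nres <<- nres + 1L
        res[[nres]] <<- cnt
      }
      return()
    }
    el <- heavy[i]
    b <- bounds[[el]]
    tailMax <- if (i < length(heavy)) tails[i + 1L] else bC[2] * mC + bH[2] * mH
    for (n in b[1]:b[2]) {
      m2 <- massSoFar + n * mono[[el]]
      if (m2 > target + tolDa) break
      if (m2 + tailMax < target - tolDa) next
      recurse(i + 1L, c(counts, stats::setNames(n, el)), m2)
    }
  }
  recurse(1L, stats::setNames(integer(0), character(0)), 0)
  if (nres == 0L)
    return(data.frame(rank = integer(0), formula = character(0),
                      calcd_mz = numeric(0), ppm = numeric(0),
                      rdbe = numeric(0), isotope_score = numeric(0)))
  cand <- lapply(res[seq_len(nres)], function(cnt) {
    f <- do.call(newFormula, as.list(cnt))
    r <- rdbe(f)
    halo <- sum(cnt[names(cnt) %in% c("Cl", "Br")])
    if (r < rdbeRange[1] || r > rdbeRange[2] || r %% 1 != 0) return(NULL)
    if (!nitrogenRuleOk(f)) return(NULL)
    if (requireHalogen && halo < 1L) return(NULL)
    calcd <- cationMz(f)
    data.frame(formula = formatFormula(f), calcd_mz = calcd,
               ppm = ppmError(mz, calcd), rdbe = r,
               hetero = sum(cnt) - sum(cnt[names(cnt) %in% c("C", "H")]),
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
  if (is.null(cand) || nrow(cand) == 0L)
    return(data.frame(rank = integer(0), formula = character(0),
                      calcd_mz = numeric(0), ppm = numeric(0),
                      rdbe = numeric(0), isotope_score = numeric(0)))
  cand$isotope_score <- NA_real_
  if (!is.null(observedPattern)) {
    cand$isotope_score <- vapply(cand$formula, function(fs) {
      scoreIsotopeFit(observedPattern, isotopologuePattern(fs))
    }, numeric(1))
  }
  scoreKey <- ifelse(is.na(cand$isotope_score), -1, cand$isotope_score)
  ord <- order(abs(cand$ppm), -scoreKey, cand$hetero, cand$formula)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  cand[, c("rank", "formula", "calcd_mz", "ppm", "rdbe", "isotope_score")]
}

.patternClusters <- function(p) {
  if (is(p, "IsotopePattern")) return(clusters(p))
  stopifnot(is.data.frame(p), all(c("mz", "abundance") %in% names(p)))
  p
}

#' Score agreement between observed and theoretical isotope patterns
#'
#' Compares an observed isotope cluster against a simulated one. Both
#' patterns are rescaled to base 100 first, so the score is invariant under
#' pattern rescaling. Scoring is restricted to the halogen-informative
#' clusters of the theoretical pattern (those at or above `mandatoryRel`
#' percent of the base peak; for Cl/Br compounds these are the A, A+2 and
#' A+4 clusters, while weak 13C satellites carry no halogen signature).
#' Each such cluster must have an observed counterpart within `mzTol`;
#' matched clusters score by abundance agreement (full credit within
#' `abTol`, linearly falling to zero at three times `abTol`), weighted by
#' theoretical abundance. A missing cluster contributes zero, and missing
#' the base cluster additionally caps the score at half the remaining
#' coverage.
#'
#' @param observed,theoretical [IsotopePattern-class] objects or data.frames
#'   with `mz` and `abundance` columns; non-empty.
#' @param mzTol Cluster matching tolerance in Da (default 0.01).
#' @param abTol Relative abundance tolerance, as a fraction of the
#'   theoretical cluster abundance (default 0.1).
#' @param mandatoryRel Percent-of-base threshold above which theoretical
#'   clusters are mandatory (default 25).
#' @return A score in `[0, 1]`; 1 for a perfect match.
#' @export
scoreIsotopeFit <- function(observed, theoretical, mzTol = 0.01, abTol = 0.1,
                            mandatoryRel = 25) {
  obs <- .patternClusters(observed)
  theo <- .patternClusters(theoretical)
  stopifnot(nrow(obs) > 0L, nrow(theo) > 0L)
  obs$abundance <- obs$abundance / max(obs$abundance) * 100
  theo$abundance <- theo$abundance / max(theo$abundance) * 100
  mand <- theo[theo$abundance >= mandatoryRel, , drop = FALSE]
  baseMissing <- FALSE
  w <- mand$abundance
  s <- numeric(nrow(mand))
  for (i in seq_len(nrow(mand))) {
    d <- abs(obs$mz - mand$mz[i])
    j <- which.min(d)
    if (d[j] > mzTol) {
      s[i] <- 0
      if (mand$abundance[i] >= 100 - 1e-9) baseMissing <- TRUE
    } else {
      relDev <- abs(obs$abundance[j] - mand$abundance[i]) / mand$abundance[i]
      s[i] <- max(0, min(1, (3 * abTol - relDev) / (2 * abTol)))
    }
  }
  score <- sum(w * s) / sum(w)
  if (baseMissing) score <- min(score, 0.5 * score)
  score
}
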