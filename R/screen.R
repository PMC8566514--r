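#' @include chem.R
NULL

## A feature table is a plain data.frame with (at least) columns
##   sample_id, mz, rt, area, snr  and optionally a list-column `cluster`
## of data.frames (mz, abundance) holding the observed isotope cluster.
## Screening stages return subsets of their input and record what they
## removed in an `audit` attribute rather than dropping rows silently.

.emptyAudit <- function() {
  data.frame(sample_id = character(0), mz = numeric(0), rt = numeric(0),
             reason = character(0), stringsAsFactors = FALSE)
}

.withAudit <- function(kept, dropped, reason, prev = NULL) {
  aud <- if (nrow(dropped))
    data.frame(sample_id = if (is.null(dropped$sample_id)) NA_character_
               else as.character(dropped$sample_id),
               mz = dropped$mz, rt = dropped$rt, reason = reason,
               stringsAsFactors = FALSE)
  else .emptyAudit()
  if (!is.null(prev)) aud <- rbind(prev, aud)
  attr(kept, "audit") <- aud
  kept
}

#' Audit trail of a screening stage
#'
#' Each screening stage flags, rather than silently discards, the features
#' it removes. This accessor returns that log.
#'
#' @param features A feature table returned by a screening stage.
#' @return data.frame with columns `sample_id`, `mz`, `rt`, `reason`.
#' @export
screenAudit <- function(features) {
  aud <- attr(features, "audit")
  if (is.null(aud)) .emptyAudit() else aud
}

#' Detect features in centroided MS1 peak frames
#'
#' A minimal deterministic feature builder: centroid peaks are grouped
#' across retention-time frames when their m/z values agree within `ppmTol`;
#' each group becomes one feature located at the retention time of its most
#' intense (apex) peak, with the apex intensity as the feature area. The
#' signal-to-noise ratio is the apex intensity divided by the median
#' intensity of peaks from other groups within a +-`snWindow` Da m/z window
#' (infinite when that window is empty).
#'
#' @param frames data.frame of centroided MS1 peaks with columns `rt`
#'   (minutes), `mz` (Da) and `intensity`.
#' @param ppmTol m/z grouping tolerance in ppm (default 5).
#' @param snWindow Half-width in Da of the noise window (default 0.5).
#' @return Feature table with columns `mz` (intensity-weighted mean), `rt`,
#'   `area`, `snr`, `n_frames`.
#' @export
detectFeatures <- function(frames, ppmTol = 5, snWindow = 0.5) {
  stopifnot(all(c("rt", "mz", "intensity") %in% names(frames)))
  if (nrow(frames) == 0L)
    return(data.frame(mz = numeric(0), rt = numeric(0), area = numeric(0),
                      snr = numeric(0), n_frames = integer(0)))
  frames <- frames[order(frames$mz), , drop = FALSE]
  gap <- diff(frames$mz) > frames$mz[-nrow(frames)] * ppmTol * 1e-6
  grp <- cumsum(c(TRUE, gap))
  feats <- lapply(split(frames, factor(grp, levels = unique(grp))),
                  function(d) {
    apex <- which.max(d$intensity)
    data.frame(mz = sum(d$mz * d$intensity) / sum(d$intensity),
               rt = d$rt[apex], area = d$intensity[apex],
               n_frames = length(unique(d$rt)))
  })
  out <- do.call(rbind, feats)
  grpOf <- stats::setNames(grp, NULL)
  out$snr <- vapply(seq_len(nrow(out)), function(i) {
    inWin <- abs(frames$mz - out$mz[i]) <= snWindow & grpOf != i
    if (!any(inWin)) return(Inf)
    out$area[i] / stats::median(frames$intensity[inWin])
  }, numeric(1))
  out <- out[order(out$mz), c("mz", "rt", "area", "snr", "n_frames")]
  rownames(out) <- NULL
  out
}

#' Eliminate features that are present in control samples
#'
#' Removes treated-group features that match any control-group feature
#' within both an m/z tolerance (ppm) and a retention-time tolerance: a
#' signal also present in untreated samples cannot be a treatment-derived
#' transformation product. Matching uses "any control replicate" semantics;
#' with `mode = "fold_change"` a treated feature is instead retained when
#' its area exceeds `foldChange` times the largest matching control area.
#' Eliminated features are recorded in the audit log (see [screenAudit()]).
#'
#' @param treated,control Feature tables (see [detectFeatures()]); both must
#'   carry `sample_id`, `mz`, `rt`, `area`.
#' @param mzTolPpm m/z tolerance in ppm (default 5).
#' @param rtTol Retention-time tolerance in minutes (default 0.1).
#' @param mode `"any_control"` (default) or `"fold_change"`.
#' @param foldChange Treated/control area ratio above which a matched
#'   feature is kept in fold-change mode (default 10).
#' @return The surviving subset of `treated`, with an audit attribute.
#' @export
subtractControl <- function(treated, control, mzTolPpm = 5, rtTol = 0.1,
                            mode = c("any_control", "fold_change"),
                            foldChange = 10) {
  mode <- match.arg(mode)
  if (nrow(treated) == 0L) return(.withAudit(treated, treated, character(0)))
  drop <- logical(nrow(treated))
  if (nrow(control) > 0L) {
    for (i in seq_len(nrow(treated))) {
      hit <- abs(control$mz - treated$mz[i]) <=
        treated$mz[i] * mzTolPpm * 1e-6 &
        abs(control$rt - treated$rt[i]) <= rtTol
      if (!any(hit)) next
      drop[i] <- if (mode == "any_control") TRUE
      else treated$area[i] < foldChange * max(control$area[hit])
    }
  }
  .withAudit(treated[!drop, , drop = FALSE],
             treated[drop, , drop = FALSE], "matched_control",
             prev = screenAudit(treated))
}

#' Apply intensity and signal-to-noise thresholds
#'
#' Retains features with `area >= minArea` and `snr > minSnr` (the
#' signal-to-noise comparison is strict).
#'
#' @param features Feature table.
#' @param minArea Minimum peak area (default 1e4).
#' @param minSnr Signal-to-noise cutoff, exclusive (default 10).
#' @return The surviving subset, with an audit attribute.
#' @export
applyThresholds <- function(features, minArea = 1e4, minSnr = 10) {
  stopifnot(minArea > 0, minSnr > 0)
  keep <- features$area >= minArea & features$snr > minSnr
  .withAudit(features[keep, , drop = FALSE],
             features[!keep, , drop = FALSE], "below_threshold",
             prev = screenAudit(features))
}

## Relative A+2/A abundance contributed by one Cl or Br atom.
.halogenA2Ratio <- function(element) {
  tab <- isotopeTable()
  d <- tab[tab$element == element, ]
  d$abundance[d$nominal == max(d$nominal)] /
    d$abundance[d$nominal == min(d$nominal)]
}

#' Cl/Br isotope filter
#'
#' Retains features whose observed isotope cluster shows an A+2 companion
#' at the halogen isotope spacing (1.997 Da within `mzTol`; the 13C2
#' satellite at +2.007 Da falls outside the default window) with an
#' A+2/A abundance ratio consistent, within a relative tolerance, with at
#' least one Cl and/or Br atom (candidate ratios are additive over up to
#' `maxHalogens` of each). Features lacking a cluster are dropped with an
#' audit note.
#'
#' @param features Feature table with a `cluster` list-column of
#'   data.frames (`mz`, `abundance`).
#' @param mzTol Tolerance on the A+2 spacing in Da (default 0.006).
#' @param ratioTol Relative tolerance on the A+2/A abundance ratio
#'   (default 0.3).
#' @param maxHalogens Largest Cl and Br count considered (default 2).
#' @return The surviving subset, with an audit attribute.
#' @export
halogenFilter <- function(features, mzTol = 0.006, ratioTol = 0.3,
                          maxHalogens = 2) {
  spacing <- 1.997
  rCl <- .halogenA2Ratio("Cl")
  rBr <- .halogenA2Ratio("Br")
  combos <- expand.grid(nCl = 0:maxHalogens, nBr = 0:maxHalogens)
  combos <- combos[combos$nCl + combos$nBr >= 1L, ]
  expected <- combos$nCl * rCl + combos$nBr * rBr
  keep <- logical(nrow(features))
  reason <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    cl <- features$cluster[[i]]
    if (is.null(cl) || nrow(cl) == 0L) {
      reason[i] <- "no_isotope_cluster"
      next
    }
    base <- which.min(abs(cl$mz - features$mz[i]))
    d <- cl$mz - cl$mz[base] - spacing
    j <- which(abs(d) <= mzTol)
    if (length(j) == 0L) {
      reason[i] <- "no_A2_companion"
      next
    }
    ratio <- max(cl$abundance[j]) / cl$abundance[base]
    if (any(abs(ratio - expected) <= ratioTol * expected)) keep[i] <- TRUE
    else reason[i] <- "A2_ratio_inconsistent"
  }
  dropped <- features[!keep, , drop = FALSE]
  out <- .withAudit(features[keep, , drop = FALSE], dropped, "halogen_filter",
                    prev = screenAudit(features))
  if (nrow(dropped)) {
    aud <- attr(out, "audit")
    aud$reason[(nrow(aud) - nrow(dropped) + 1L):nrow(aud)] <-
      reason[!keep]
    attr(out, "audit") <- aud
  }
  out
}

#' Match features against a suspect list
#'
#' Pairs features with suspect-list entries whose expected m/z agrees
#' within `mzTolPpm`; when the suspect carries an expected retention time,
#' the feature must also fall within `rtTol` minutes of it, which is what
#' separates isobaric suspects eluting at different times.
#'
#' @param features Feature table.
#' @param suspects data.frame with columns `name`, `formula`,
#'   `expected_mz` and optionally `expected_rt` (NA allowed per row).
#' @param mzTolPpm m/z tolerance in ppm (default 5).
#' @param rtTol Retention-time tolerance in minutes, applied only when the
#'   suspect's `expected_rt` is known (default 0.1).
#' @return data.frame of (feature, suspect) pairs: the feature columns plus
#'   `name`, `formula`, `expected_mz`, `expected_rt`, `ppm`.
#' @export
matchSuspects <- function(features, suspects, mzTolPpm = 5, rtTol = 0.1) {
  stopifnot(all(c("name", "expected_mz") %in% names(suspects)))
  if (!"expected_rt" %in% names(suspects)) suspects$expected_rt <- NA_real_
  out <- list()
  featCols <- setdiff(names(features), "cluster")
  for (i in seq_len(nrow(features))) {
    dppm <- ppmError(features$mz[i], suspects$expected_mz)
    ok <- abs(dppm) <= mzTolPpm &
      (is.na(suspects$expected_rt) |
         abs(features$rt[i] - suspects$expected_rt) <= rtTol)
    for (j in which(ok)) {
      out[[length(out) + 1L]] <- cbind(
        features[i, featCols, drop = FALSE],
        data.frame(name = suspects$name[j],
                   formula = if ("formula" %in% names(suspects))
                     as.character(suspects$formula[j]) else NA_character_,
                   expected_mz = suspects$expected_mz[j],
                   expected_rt = suspects$expected_rt[j],
                   ppm = dppm[j], stringsAsFactors = FALSE))
    }
  }
  if (!length(out))
    return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a targeted mass inclusion list
#'
#' Deduplicates candidate m/z values for data-dependent MS2 acquisition:
#' values within `massTolPpm` of the running entry are merged (their mean
#' becomes the entry m/z), and entries are returned sorted ascending.
#'
#' @param mzValues Numeric vector of candidate `[M+H]+` m/z values.
#' @param massTolPpm Merge/isolation tolerance in ppm (default 25).
#' @return data.frame with columns `mz` and `ppm_tol`, one row per entry.
#' @export
buildInclusionList <- function(mzValues, massTolPpm = 25) {
  stopifnot(all(mzValues > 0))
  if (length(mzValues) == 0L)
    return(data.frame(mz = numeric(0), ppm_tol = numeric(0)))
  mz <- sort(mzValues)
  groups <- list()
  cur <- mz[1]
  for (x in mz[-1]) {
    if ((x - mean(cur)) / mean(cur) * 1e6 <= massTolPpm) cur <- c(cur, x)
    else {
      groups[[length(groups) + 1L]] <- cur
      cur <- x
    }
  }
  groups[[length(groups) + 1L]] <- cur
  data.frame(mz = vapply(groups, mean, numeric(1)), ppm_tol = massTolPpm)
}
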