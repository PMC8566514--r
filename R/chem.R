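#' @include AllClasses.R AllGenerics.R
NULL

## Coerce character -> ElementalFormula where convenient.
.asFormula <- function(f) {
  if (is(f, "ElementalFormula")) f else parseFormula(f)
}

#' Construct an elemental formula from counts
#'
#' @param ... Named atom counts, e.g. `newFormula(C = 6, H = 10, O = 5)`.
#' @return An [ElementalFormula-class] object. Zero counts are dropped.
#' @export
newFormula <- function(...) {
  cnt <- c(...)
  if (is.null(names(cnt)) || any(names(cnt) == ""))
    stop("all atom counts must be named by element symbol")
  cnt <- cnt[cnt != 0]
  ## canonical Hill order: C, H, then remaining symbols alphabetically
  ord <- c("C", "H", setdiff(sort(supportedElements()), c("C", "H")))
  cnt <- cnt[order(match(names(cnt), ord))]
  new("ElementalFormula", counts = stats::setNames(as.integer(cnt), names(cnt)))
}

#' Parse a Hill-notation formula string
#'
#' Parses strings such as `"C19H14BrClN6O2"` into an element-count map.
#' Only the elements in [supportedElements()] are accepted; an unknown
#' symbol or a malformed multiplier is an error, not a silent drop.
#'
#' @param text A single non-empty formula string in Hill notation.
#' @return An [ElementalFormula-class] object.
#' @examples
#' parseFormula("C19H14BrClN6O2")
#' parseFormula("C6H10O5")
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  ## tokenize; any residue not consumed by element+count tokens is malformed
  rx <- "([A-Z][a-z]?)([0-9]*)"
  tokens <- regmatches(text, gregexpr(rx, text))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (sum(nchar(tokens)) != nchar(text))
    stop("malformed formula string: ", text)
  el <- sub("[0-9]*$", "", tokens)
  bad <- setdiff(el, supportedElements())
  if (length(bad))
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  n <- sub("^[A-Za-z]+", "", tokens)
  if (any(n == "0"))
    stop("malformed multiplier 0 in formula string: ", text)
  n <- ifelse(n == "", 1L, suppressWarnings(as.integer(n)))
  if (anyNA(n)) stop("malformed multiplier in formula string: ", text)
  cnt <- tapply(n, el, sum)
  do.call(newFormula, as.list(cnt))
}

#' Format an elemental formula in Hill notation
#'
#' @param f An [ElementalFormula-class] object (or formula string).
#' @return A single character string; round-trips through [parseFormula()].
#' @export
formatFormula <- function(f) {
  cnt <- elementCounts(.asFormula(f))
  paste0(names(cnt), ifelse(cnt == 1L, "", cnt), collapse = "")
}

#' Add two elemental formulas
#'
#' Element-wise sum of the atom counts; mass is additive over the union.
#'
#' @param f,g [ElementalFormula-class] objects or formula strings.
#' @return An [ElementalFormula-class] object.
#' @export
addFormulas <- function(f, g) {
  a <- elementCounts(.asFormula(f))
  b <- elementCounts(.asFormula(g))
  el <- union(names(a), names(b))
  tot <- stats::setNames(integer(length(el)), el)
  tot[names(a)] <- tot[names(a)] + a
  tot[names(b)] <- tot[names(b)] + b
  do.call(newFormula, as.list(tot))
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum of the atomic masses of the most abundant isotope of each atom.
#'
#' @param f An [ElementalFormula-class] object or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopicMass("C6H10O5")  # anhydroglucose, 162.0528
#' @export
monoisotopicMass <- function(f) {
  cnt <- elementCounts(.asFormula(f))
  sum(.monoMasses()[names(cnt)] * cnt)
}

#' Nominal (integer) mass of a neutral formula
#'
#' Sum of the mass numbers of the most abundant isotopes; the quantity whose
#' parity the nitrogen rule constrains.
#'
#' @inheritParams monoisotopicMass
#' @return Integer nominal mass.
#' @export
nominalMass <- function(f) {
  cnt <- elementCounts(.asFormula(f))
  as.integer(sum(.nominalMasses()[names(cnt)] * cnt))
}

#' m/z of a singly protonated cation
#'
#' For an `[M+H]+` ion: neutral monoisotopic mass, plus one hydrogen atom,
#' minus one electron mass. The electron-mass subtraction matters at the
#' fourth decimal place for accurate-mass work.
#'
#' @param f Neutral [ElementalFormula-class] object or formula string.
#' @param adduct Adduct specification; only `"M+H"` (charge +1) is supported.
#' @return Ion m/z in Da.
#' @examples
#' cationMz("C19H14BrClN6O2")  # cyantraniliprole [M+H]+, 473.0123
#' @export
cationMz <- function(f, adduct = "M+H") {
  if (!identical(adduct, "M+H"))
    stop("unsupported adduct: ", adduct, " (only M+H is implemented)")
  monoisotopicMass(f) + .monoMasses()[["H"]] - .ELECTRON_MASS
}

#' Signed mass error in parts per million
#'
#' @param observed_mz,reference_mz Observed and reference m/z values (Da);
#'   vectorized, `reference_mz > 0`.
#' @return `(observed - reference) / reference * 1e6`.
#' @examples
#' ppmError(455.0022, 455.0017)  # 1.1 ppm at 1 dp
#' @export
ppmError <- function(observed_mz, reference_mz) {
  stopifnot(all(reference_mz > 0))
  (observed_mz - reference_mz) / reference_mz * 1e6
}

#' Ring plus double bond equivalents
#'
#' Valence-based unsaturation index `C + 1 + (N - H - Cl - Br) / 2`, used as
#' a plausibility filter during formula enumeration. Half-integral values
#' indicate an ion or radical rather than an even-electron neutral molecule.
#'
#' @inheritParams monoisotopicMass
#' @return RDBE value (possibly half-integral).
#' @examples
#' rdbe("C19H14BrClN6O2")  # 15
#' @export
rdbe <- function(f) {
  cnt <- elementCounts(.asFormula(f))
  g <- function(e) if (e %in% names(cnt)) cnt[[e]] else 0L
  g("C") + 1 + (g("N") - g("H") - g("Cl") - g("Br")) / 2
}

#' Nitrogen-rule check for a neutral molecule
#'
#' An even-electron neutral molecule containing C, H, N, O, S, Cl and Br has
#' an odd nominal mass if and only if it contains an odd number of nitrogen
#' atoms. Implausible formulas violating this parity are rejected during
#' enumeration.
#'
#' @inheritParams monoisotopicMass
#' @return `TRUE` if the parity relation holds.
#' @examples
#' nitrogenRuleOk("NH3")             # TRUE (nominal 17, one N)
#' nitrogenRuleOk("C19H14BrClN6O2")  # TRUE (nominal 472, six N)
#' @export
nitrogenRuleOk <- function(f) {
  cnt <- elementCounts(.asFormula(f))
  nN <- if ("N" %in% names(cnt)) cnt[["N"]] else 0L
  (nominalMass(.asFormula(f)) %% 2L == 1L) == (nN %% 2L == 1L)
}

## ---- isotopologue simulation --------------------------------------------

## Distribution of one element repeated n times, as exact convolution of the
## single-atom isotope distribution with itself (exponentiation by squaring).
## Peaks with probability below `pruneAbs` are dropped; identical-composition
## duplicates cannot arise so no merge step is needed beyond near-equal
## masses produced by floating-point association, which we aggregate.
.elementDist <- function(element, n, pruneAbs = 1e-15) {
  tab <- isotopeTable()
  d <- tab[tab$element == element, c("mass_da", "abundance")]
  names(d) <- c("mass", "prob")
  if (n == 0L) return(data.frame(mass = 0, prob = 1))
  acc <- NULL
  base <- d
  while (n > 0L) {
    if (n %% 2L == 1L)
      acc <- if (is.null(acc)) base else .convolve2(acc, base, pruneAbs)
    n <- n %/% 2L
    if (n > 0L) base <- .convolve2(base, base, pruneAbs)
  }
  acc
}

.convolve2 <- function(a, b, pruneAbs) {
  mass <- outer(a$mass, b$mass, `+`)
  prob <- outer(a$prob, b$prob)
  out <- data.frame(mass = as.vector(mass), prob = as.vector(prob))
  ## aggregate numerically identical masses (to 1e-9 Da) to keep sizes small
  key <- round(out$mass, 9)
  agg <- rowsum(out$prob, key)
  out <- data.frame(mass = as.numeric(rownames(agg)), prob = agg[, 1])
  out <- out[out$prob > pruneAbs, , drop = FALSE]
  out[order(out$mass), , drop = FALSE]
}

#' Exact isotopologue peaks of an ion
#'
#' Full isotopologue fine structure of an `[M+H]+` ion by exact convolution
#' over the isotope distributions of every atom, before any binning. Mainly
#' useful for validation; most callers want [isotopologuePattern()].
#'
#' @inheritParams cationMz
#' @param pruneAbs Absolute probability below which isotopologues are
#'   dropped during convolution.
#' @return data.frame with columns `mz` (Da, electron mass subtracted) and
#'   `prob` (absolute probability; sums to 1 up to pruning loss), sorted by
#'   ascending `mz`.
#' @export
isotopePeaks <- function(f, adduct = "M+H", pruneAbs = 1e-15) {
  if (!identical(adduct, "M+H"))
    stop("unsupported adduct: ", adduct)
  ion <- addFormulas(.asFormula(f), newFormula(H = 1))
  cnt <- elementCounts(ion)
  acc <- data.frame(mass = 0, prob = 1)
  for (el in names(cnt))
    acc <- .convolve2(acc, .elementDist(el, cnt[[el]], pruneAbs), pruneAbs)
  data.frame(mz = acc$mass - .ELECTRON_MASS, prob = acc$prob)
}

#' Binned isotopologue pattern of an ion
#'
#' Simulates the isotope pattern of an `[M+H]+` ion: exact convolution over
#' all atoms, then aggregation of isotopologues whose m/z values fall within
#' `bin` Da of the cluster start into clusters with abundance-weighted
#' centroid m/z, normalized so the base cluster is 100. Each cluster also
#' reports the m/z of its single most abundant isotopologue (`species_mz`),
#' since printed reference-ion values in the literature may refer to either
#' quantity.
#'
#' @inheritParams cationMz
#' @param prune Relative-abundance threshold in percent of the base cluster;
#'   weaker clusters are dropped (default 0.01).
#' @param bin Aggregation bin in Da (default 0.01, merging the fine
#'   structure within one nominal-mass cluster).
#' @return An [IsotopePattern-class] object.
#' @examples
#' isotopologuePattern("C19H14BrClN6O2")  # Br/Cl triplet at 473/475/477
#' @export
isotopologuePattern <- function(f, adduct = "M+H", prune = 0.01, bin = 0.01) {
  pk <- isotopePeaks(f, adduct)
  rawTotal <- sum(pk$prob)
  ## greedy clustering on sorted m/z, anchored at each cluster's first peak
  start <- pk$mz[1]
  id <- integer(nrow(pk))
  cur <- 1L
  for (i in seq_len(nrow(pk))) {
    if (pk$mz[i] - start > bin) {
      cur <- cur + 1L
      start <- pk$mz[i]
    }
    id[i] <- cur
  }
  mono <- pk$mz[1]
  agg <- lapply(split(pk, id), function(d) {
    data.frame(mz = sum(d$mz * d$prob) / sum(d$prob),
               abundance = sum(d$prob),
               species_mz = d$mz[which.max(d$prob)],
               nominal_shift = as.integer(round(d$mz[which.max(d$prob)] - mono)))
  })
  cl <- do.call(rbind, agg)
  cl$abundance <- cl$abundance / max(cl$abundance) * 100
  cl <- cl[cl$abundance >= prune, , drop = FALSE]
  cl <- cl[order(cl$mz), , drop = FALSE]
  rownames(cl) <- NULL
  new("IsotopePattern", clusters = cl, binWidth = bin, pruneRel = prune,
      rawTotal = rawTotal)
}
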