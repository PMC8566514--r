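## Embedded physical constants. The isotope table itself is packaged as
## structured text (inst/extdata/isotopes.csv) so that the numbers the whole
## package rests on are inspectable and diffable; it is read once per session.

.haloscreen_env <- new.env(parent = emptyenv())

#' Supported chemical elements
#'
#' The element set covered by all formula arithmetic in this package.
#'
#' @return Character vector of element symbols.
#' @export
supportedElements <- function() c("C", "H", "N", "O", "S", "Cl", "Br")

## Electron rest mass in Da (CODATA).
.ELECTRON_MASS <- 0.000548579909

#' Isotope masses and abundances
#'
#' Returns the embedded table of isotopic masses (Da) and representative
#' abundances used throughout the package, one row per stable isotope of the
#' supported elements. Values follow the NIST compilation; the packaged CSV
#' carries a version stamp in its header comment.
#'
#' @return A data.frame with columns `element`, `isotope`, `mass_da`,
#'   `abundance` and `nominal` (integer mass number).
#' @examples
#' subset(isotopeTable(), element == "Cl")
#' @export
isotopeTable <- function() {
  tab <- .haloscreen_env$isotopes
  if (is.null(tab)) {
    path <- system.file("extdata", "isotopes.csv", package = "haloscreen",
                        mustWork = TRUE)
    tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    stopifnot(all(tab$element %in% supportedElements()),
              all(tab$abundance > 0), all(tab$mass_da > 0))
    ## abundances of each element must sum to 1 (they do, by construction)
    tot <- tapply(tab$abundance, tab$element, sum)
    stopifnot(all(abs(tot - 1) < 1e-9))
    .haloscreen_env$isotopes <- tab
  }
  tab
}

#' Electron rest mass
#'
#' @return Electron mass in Da, as subtracted from singly protonated cations.
#' @export
electronMass <- function() .ELECTRON_MASS

## Named vector of monoisotopic (most abundant isotope) masses.
.monoMasses <- function() {
  m <- .haloscreen_env$mono
  if (is.null(m)) {
    tab <- isotopeTable()
    sp <- split(tab, tab$element)
    m <- vapply(sp, function(d) d$mass_da[which.max(d$abundance)], numeric(1))
    .haloscreen_env$mono <- m
  }
  m
}

## Named vector of nominal (integer) masses of the most abundant isotopes.
.nominalMasses <- function() {
  m <- .haloscreen_env$nominal
  if (is.null(m)) {
    tab <- isotopeTable()
    sp <- split(tab, tab$element)
    m <- vapply(sp, function(d) as.numeric(d$nominal[which.max(d$abundance)]),
                numeric(1))
    .haloscreen_env$nominal <- m
  }
  m
}

#' Round half away from zero
#'
#' Fixed-point rounding with ties going away from zero, the convention used
#' when comparing computed values against printed tables (base [round()] uses
#' round-half-to-even, which disagrees on exact ties such as 2.45 -> 2.4).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' roundHalfUp(2.45, 1)   # 2.5
#' round(2.45, 1)         # 2.4
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}
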