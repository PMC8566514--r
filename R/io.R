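#' @include chem.R annotate.R
NULL

## All tabular interchange is comma-separated UTF-8 with a mandatory header
## row and decimal points; spectra travel as MGF (MS2) or long CSV peak
## frames (MS1).

.extdata <- function(file) {
  system.file("extdata", file, package = "haloscreen", mustWork = TRUE)
}

#' Load the packaged cyantraniliprole metabolite table
#'
#' Reads the curated suspect table of cyantraniliprole and its 21 plant
#' transformation products (name, formula, retention time, calculated and
#' observed `[M+H]+` m/z, ppm error, MS2 fragment ions, tissue occurrence
#' flags, identification confidence level, transformation phase and
#' literature provenance), and validates it on every load: exactly one
#' parent plus 21 metabolites, every calculated m/z consistent with
#' [cationMz()] of its formula, every formula passing the nitrogen rule,
#' and an 11 / 6 / 4 phase-I / phase-II / breakdown partition.
#'
#' @param path Optional path to an alternative CSV with the same columns
#'   (defaults to the packaged table).
#' @param validate Run the consistency checks (default `TRUE`).
#' @return data.frame with one row per compound; `fragment_ions` is a
#'   list-column of numeric vectors (empty when no MS2 fragments were
#'   observed).
#' @examples
#' tab <- loadMetaboliteTable()
#' nrow(tab)  # 22
#' @export
loadMetaboliteTable <- function(path = NULL, validate = TRUE) {
  if (is.null(path)) path <- .extdata("table1_metabolites.csv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(fragment_ions = "character"))
  tab$fragment_ions <- lapply(strsplit(tab$fragment_ions, ";", fixed = TRUE),
                              function(x) as.numeric(x[nzchar(x)]))
  if (validate) {
    if (nrow(tab) != 22L || sum(tab$phase == "parent") != 1L)
      stop("metabolite table must contain 1 parent + 21 metabolites")
    dev <- vapply(seq_len(nrow(tab)), function(i)
      abs(cationMz(tab$formula[i]) - tab$calcd_mz[i]), numeric(1))
    ## printed values are rounded to 4 dp (one is truncated), so allow 1e-4
    if (any(dev > 1.1e-4))
      stop("calcd_mz inconsistent with formula for: ",
           paste(tab$name[dev > 1.1e-4], collapse = ", "))
    nr <- vapply(tab$formula, nitrogenRuleOk, logical(1))
    if (!all(nr))
      stop("nitrogen rule violated for: ",
           paste(tab$name[!nr], collapse = ", "))
    phases <- table(tab$phase[tab$phase != "parent"])
    if (!identical(as.integer(phases[c("phase_I", "phase_II", "breakdown")]),
                   c(11L, 6L, 4L)))
      stop("phase partition must be 11 phase_I / 6 phase_II / 4 breakdown")
    if (!all(tab$level %in% c("1", "2a", "2b", "3", "4", "5")))
      stop("invalid confidence level in table")
    if (!all(unlist(tab[, c("leaves", "flowers", "fruits")]) %in% c("+", "-")))
      stop("occurrence flags must be '+' or '-'")
  }
  tab
}

#' Suspect list derived from the packaged metabolite table
#'
#' @param table A metabolite table from [loadMetaboliteTable()].
#' @return data.frame with columns `name`, `formula`, `expected_mz`
#'   (theoretical `[M+H]+` m/z from the formula), `expected_rt`, `source`,
#'   suitable for [matchSuspects()].
#' @export
suspectList <- function(table = loadMetaboliteTable()) {
  data.frame(name = table$name, formula = table$formula,
             expected_mz = vapply(table$formula, cationMz, numeric(1)),
             expected_rt = table$rt_min, source = table$source,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Load the fragment rule set
#'
#' The MS2 annotation rules are data, not code: generic neutral losses
#' (packaged CSV: anhydroglucose, water, HCl, HBr, CO, HCN, methylamine)
#' plus per-compound characteristic ions taken from the metabolite table's
#' fragment lists. Users can pass their own neutral-loss CSV or extend the
#' returned data.frame.
#'
#' @param compound Optional compound name: restrict the characteristic
#'   ions to that compound (generic neutral losses are always included).
#' @param lossesPath Optional path to an alternative neutral-loss CSV with
#'   columns `kind`, `mz_or_mass`, `label`.
#' @param table Metabolite table supplying the characteristic ions.
#' @return data.frame with columns `kind`, `mz_or_mass`, `label`,
#'   `compound` (NA for generic rules).
#' @export
loadFragmentRules <- function(compound = NULL, lossesPath = NULL,
                              table = loadMetaboliteTable()) {
  if (is.null(lossesPath)) lossesPath <- .extdata("neutral_losses.csv")
  losses <- utils::read.csv(lossesPath, stringsAsFactors = FALSE)
  losses$compound <- NA_character_
  ions <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
    fr <- table$fragment_ions[[i]]
    if (!length(fr)) return(NULL)
    data.frame(kind = "characteristic_ion", mz_or_mass = fr,
               label = paste0(table$name[i], " ion ", fr),
               compound = table$name[i], stringsAsFactors = FALSE)
  }))
  if (!is.null(compound))
    ions <- ions[ions$compound %in% compound, , drop = FALSE]
  rbind(losses, ions)
}

#' Load the transformation pathway edge list
#'
#' @param path Optional path to an alternative CSV with columns `from`,
#'   `to`, `reaction`, `reaction_class`.
#' @return data.frame of pathway edges for [classifyPhase()].
#' @export
loadPathwayEdges <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("pathway_edges.csv")
  edges <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(edges$reaction_class %in%
                  c("functionalization", "conjugation", "cleavage")))
  edges
}

## ---- MGF -----------------------------------------------------------------

#' Read an MGF file of MS2 spectra
#'
#' Minimal Mascot Generic Format reader: one spectrum per
#' `BEGIN IONS`/`END IONS` block, with `TITLE`, `PEPMASS` and `RTINSECONDS`
#' headers recognized. Malformed content is reported with its line number.
#'
#' @param path Path to an MGF file.
#' @return List of spectra; each a list with `title`, `precursor_mz`,
#'   `rt_seconds` and a `peaks` data.frame (`mz`, `intensity`).
#' @export
readMgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (ln == "BEGIN IONS") {
      if (!is.null(cur)) stop("line ", i, ": nested BEGIN IONS")
      cur <- list(title = NA_character_, precursor_mz = NA_real_,
                  rt_seconds = NA_real_, mz = numeric(0),
                  intensity = numeric(0))
    } else if (ln == "END IONS") {
      if (is.null(cur)) stop("line ", i, ": END IONS without BEGIN IONS")
      spectra[[length(spectra) + 1L]] <-
        list(title = cur$title, precursor_mz = cur$precursor_mz,
             rt_seconds = cur$rt_seconds,
             peaks = data.frame(mz = cur$mz, intensity = cur$intensity))
      cur <- NULL
    } else if (is.null(cur)) {
      stop("line ", i, ": content outside BEGIN/END IONS block")
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- toupper(kv[1])
      val <- paste(kv[-1], collapse = "=")
      if (key == "TITLE") cur$title <- val
      if (key == "PEPMASS")
        cur$precursor_mz <- as.numeric(strsplit(val, "[ \t]+")[[1]][1])
      if (key == "RTINSECONDS") cur$rt_seconds <- as.numeric(val)
    } else {
      xs <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
      if (length(xs) < 2L || anyNA(xs[1:2]))
        stop("line ", i, ": malformed peak line: ", lines[i])
      cur$mz <- c(cur$mz, xs[1])
      cur$intensity <- c(cur$intensity, xs[2])
    }
  }
  if (!is.null(cur)) stop("truncated file: unterminated BEGIN IONS block")
  spectra
}

#' Write MS2 spectra to an MGF file
#'
#' @param spectra List of spectra as returned by [readMgf()].
#' @param path Output path.
#' @return Invisibly, `path`. Numeric values are written with enough
#'   digits to round-trip at 6 decimal places.
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.na(sp$title)) writeLines(paste0("TITLE=", sp$title), con)
    if (!is.na(sp$precursor_mz))
      writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    if (!is.null(sp$rt_seconds) && !is.na(sp$rt_seconds))
      writeLines(sprintf("RTINSECONDS=%.4f", sp$rt_seconds), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

## ---- MS1 peak frames -----------------------------------------------------

#' Read or write MS1 centroid peak frames as CSV
#'
#' Long-format centroid peak lists with columns `rt` (minutes), `mz` (Da)
#' and `intensity`, the MS1 dialect consumed by [detectFeatures()]. The
#' reader validates the schema and reports the file; values round-trip at
#' 6 decimal places.
#'
#' @param path File path.
#' @param frames data.frame of peaks to write.
#' @return `readPeakFrames` returns the validated data.frame;
#'   `writePeakFrames` invisibly returns `path`.
#' @export
readPeakFrames <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rt", "mz", "intensity")
  if (!all(need %in% names(d)))
    stop("peak frame CSV must have columns rt, mz, intensity: ", path)
  bad <- which(!stats::complete.cases(d[need]) | d$mz <= 0)
  if (length(bad))
    stop("malformed peak rows (data line ", bad[1], ") in ", path)
  d
}

#' @rdname readPeakFrames
#' @export
writePeakFrames <- function(frames, path) {
  stopifnot(all(c("rt", "mz", "intensity") %in% names(frames)))
  out <- frames
  out$rt <- round(out$rt, 6)
  out$mz <- round(out$mz, 6)
  out$intensity <- round(out$intensity, 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
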