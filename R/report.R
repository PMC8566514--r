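#' @include AllClasses.R
NULL

## Study tables are tidy long data.frames keyed by
## (compound, tissue, dat, replicate) with an `area` (or `concentration`)
## value column; replicate summaries use the sample standard deviation.

#' Metabolite-to-parent ratio kinetics
#'
#' Normalizes each metabolite's signal to the parent compound's signal in
#' the same (tissue, days-after-treatment, replicate) cell and summarizes
#' across replicates, yielding the M/P ratio in percent. By default the
#' ratio is formed per replicate and then averaged (mean of ratios);
#' `method = "ratio_of_means"` divides the replicate means instead. Cells
#' whose parent signal is zero or missing are flagged, not silently
#' dropped. Ratios are scale-invariant: multiplying every area in a cell
#' by a constant leaves them unchanged.
#'
#' @param table Tidy study table: data.frame with columns `compound`,
#'   `tissue`, `dat`, `replicate` and `area`.
#' @param parent Parent compound identifier (default `"Cyantraniliprole"`).
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return data.frame with one row per (compound, tissue, dat):
#'   `mp_ratio_pct` (mean), `sd`, `n`, `flag` (`"ok"`,
#'   `"parent_missing"` or `"parent_zero"`). The parent's own rows are 100
#'   with sd 0.
#' @export
mpRatios <- function(table, parent = "Cyantraniliprole",
                     method = c("mean_of_ratios", "ratio_of_means")) {
  method <- match.arg(method)
  need <- c("compound", "tissue", "dat", "replicate", "area")
  stopifnot(all(need %in% names(table)))
  par <- table[table$compound == parent, ]
  key <- function(d) paste(d$tissue, d$dat, d$replicate, sep = "\r")
  parArea <- stats::setNames(par$area, key(par))
  cellKey <- paste(table$tissue, table$dat, sep = "\r")
  out <- lapply(split(table, list(table$compound, cellKey), drop = TRUE,
                      sep = "\r"),
                function(d) {
    pa <- parArea[key(d)]
    flag <- if (anyNA(pa)) "parent_missing"
            else if (any(pa == 0)) "parent_zero" else "ok"
    if (flag != "ok") {
      ratio <- mn <- sdv <- NA_real_
    } else if (method == "mean_of_ratios") {
      ratio <- d$area / pa * 100
      mn <- mean(ratio)
      sdv <- if (length(ratio) > 1L) stats::sd(ratio) else NA_real_
    } else {
      mn <- mean(d$area) / mean(pa) * 100
      sdv <- NA_real_
    }
    data.frame(compound = d$compound[1], tissue = d$tissue[1],
               dat = d$dat[1], mp_ratio_pct = mn, sd = sdv,
               n = nrow(d), flag = flag, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$compound, res$tissue, res$dat), ]
  rownames(res) <- NULL
  res
}

#' Tissue occurrence matrix
#'
#' Collapses confirmed hits into per-compound detected / not-detected flags
#' per tissue: a compound is `+` in a tissue if it has at least one hit in
#' at least one sample of that tissue, else `-`.
#'
#' @param hits data.frame with columns `compound` and `tissue` (one row
#'   per confident hit; other columns ignored).
#' @param compounds Compounds to report (rows); defaults to those present
#'   in `hits`.
#' @param tissues Tissues to report (columns); defaults to those present.
#' @return Character matrix of `"+"` / `"-"` with compounds as rows and
#'   tissues as columns.
#' @export
occurrenceMatrix <- function(hits, compounds = NULL, tissues = NULL) {
  if (is.null(compounds)) compounds <- sort(unique(hits$compound))
  if (is.null(tissues)) tissues <- sort(unique(hits$tissue))
  m <- matrix("-", nrow = length(compounds), ncol = length(tissues),
              dimnames = list(compounds, tissues))
  if (nrow(hits)) {
    present <- unique(hits[, c("compound", "tissue")])
    present <- present[present$compound %in% compounds &
                         present$tissue %in% tissues, ]
    m[cbind(as.character(present$compound),
            as.character(present$tissue))] <- "+"
  }
  m
}

#' Replicate summaries of a study time series
#'
#' Arithmetic mean and sample standard deviation per group cell, the form
#' in which residue time courses are reported (mean +- sd over replicate
#' plants). A cell with a single replicate reports its value with an
#' undefined (NA) standard deviation and is flagged.
#'
#' @param table Tidy study table (see [mpRatios()]).
#' @param value Name of the value column to summarize (default `"area"`).
#' @param groupKeys Grouping columns (default compound, tissue, dat).
#' @return data.frame with the group keys plus `mean`, `sd`, `n`, `flag`.
#' @export
summarizeTimeseries <- function(table, value = "area",
                                groupKeys = c("compound", "tissue", "dat")) {
  stopifnot(value %in% names(table), all(groupKeys %in% names(table)))
  keyStr <- do.call(paste, c(table[groupKeys], sep = "\r"))
  out <- lapply(split(table, factor(keyStr, levels = unique(keyStr))),
                function(d) {
    cbind(d[1, groupKeys, drop = FALSE],
          data.frame(mean = mean(d[[value]]),
                     sd = if (nrow(d) > 1L) stats::sd(d[[value]]) else NA_real_,
                     n = nrow(d),
                     flag = if (nrow(d) > 1L) "ok" else "single_replicate",
                     stringsAsFactors = FALSE))
  })
  res <- do.call(rbind, out)
  ord <- do.call(order, res[groupKeys])
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}
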