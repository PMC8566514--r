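## Independent brute-force oracles used to validate the fast implementations.
## These deliberately share no code path with the package internals: the
## isotope oracle enumerates isotope compositions with multinomial
## probabilities, and the formula oracle is a plain nested grid search.

## all length(k) non-negative integer vectors summing to n
.compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1))
  out <- list()
  for (i in 0:n) {
    rest <- .compositions(n - i, k - 1L)
    out[[length(out) + 1L]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}

## exact isotopologue distribution of n atoms of one element, by
## enumerating isotope compositions with multinomial probabilities
oracleElementDist <- function(element, n) {
  tab <- isotopeTable()
  iso <- tab[tab$element == element, ]
  if (n == 0L) return(data.frame(mass = 0, prob = 1))
  comps <- .compositions(n, nrow(iso))
  data.frame(
    mass = as.vector(comps %*% iso$mass_da),
    prob = apply(comps, 1, function(k) dmultinom(k, prob = iso$abundance)))
}

## exact [M+H]+ isotopologue peaks by direct product over elements
oracleIsotopePeaks <- function(formula) {
  cnt <- elementCounts(addFormulas(formula, newFormula(H = 1)))
  dists <- lapply(names(cnt), function(el) oracleElementDist(el, cnt[[el]]))
  grid <- expand.grid(lapply(dists, function(d) seq_len(nrow(d))))
  mz <- rowSums(mapply(function(d, idx) d$mass[idx], dists,
                       grid, SIMPLIFY = TRUE)) - electronMass()
  prob <- apply(mapply(function(d, idx) d$prob[idx], dists, grid,
                       SIMPLIFY = TRUE), 1, prod)
  agg <- rowsum(prob, round(mz, 7))
  data.frame(mz = as.numeric(rownames(agg)), prob = agg[, 1])
}

## plain grid-search formula enumeration over small bounds; the exhaustive
## candidate masses are computed by matrix arithmetic (independent of the
## package's recursive search) and only the ppm survivors are re-checked
## one by one through the rule filters
bruteForceFormulas <- function(mz, tol, bounds, requireHalogen = TRUE) {
  grid <- as.matrix(expand.grid(lapply(bounds, function(b) b[1]:b[2])))
  tabIso <- isotopeTable()
  mono <- vapply(colnames(grid), function(el) {
    d <- tabIso[tabIso$element == el, ]
    d$mass_da[which.max(d$abundance)]
  }, numeric(1))
  ionMz <- as.vector(grid %*% mono) + mono["H"] - electronMass()
  hit <- which(abs((mz - ionMz) / ionMz * 1e6) <= tol &
                 rowSums(grid) > 0)
  keep <- character(0)
  for (i in hit) {
    cnt <- grid[i, ]
    cnt <- cnt[cnt > 0]
    f <- do.call(newFormula, as.list(cnt))
    if (!nitrogenRuleOk(f)) next
    r <- rdbe(f)
    if (r < 0 || r > 40 || r %% 1 != 0) next
    halo <- sum(cnt[names(cnt) %in% c("Cl", "Br")])
    if (requireHalogen && halo < 1) next
    keep <- c(keep, formatFormula(f))
  }
  sort(keep)
}

## the packaged compound table, loaded once for all test files
fixtureTable <- loadMetaboliteTable()

## scaled-down synthetic study configuration used across tests: two
## tissues, four sampling intervals, three replicates
scaledStudyConfig <- function() {
  cfg <- studyConfig(nReplicates = 3,
                     tissues = c("mature_leaves", "flowers"))
  cfg$tissues$mature_leaves$dats <- c(14, 28, 56, 84)
  cfg$tissues$flowers$dats <- c(14, 21, 35, 49)
  cfg
}
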