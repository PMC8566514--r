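---
title: "Halogen-targeted suspect screening of pesticide transformation products"
author: "haloscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Halogen-targeted suspect screening of pesticide transformation products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haloscreen)
```

## The problem

Systemic insecticides taken up from soil are transformed inside the plant
into a cascade of phase-I products (ring closure, demethylation,
hydroxylation, dehalogenation), phase-II conjugates (glycosides, amino-acid
conjugates) and breakdown products. Characterizing this metabolite profile
from LC-HRMS data without authentic standards rests on a small set of
filters that this package implements as tested, reusable primitives. The
worked system is cyantraniliprole (C19H14BrClN6O2), a diamide insecticide
whose one bromine and one chlorine make every plausible transformation
product carry a diagnostic isotope signature; a curated table of the parent
and 21 of its tomato transformation products
(`loadMetaboliteTable()`) serves as suspect list, fragment-rule source and
regression surface.

## Exact-mass arithmetic

All mass arithmetic runs over an embedded, version-stamped isotope table
(`isotopeTable()`) restricted to C, H, N, O, S, Cl and Br. A protonated
molecular ion is

$$ m/z\,[\mathrm{M+H}]^+ \;=\; M_{\mathrm{mono}} + m_\mathrm{H} - m_e, $$

with the electron mass subtracted: at the fourth decimal place this is not
optional (the parent computes to 473.0123 with it and 473.0128 without).
Mass errors are reported as signed ppm, $(obs - ref)/ref \times 10^6$.
Comparisons against printed tables use `roundHalfUp()`, fixed-point
rounding with ties away from zero, because half-to-even rounding disagrees
with printed values on exact ties. Two ppm conventions are exposed: "table
mode" (against a 4-decimal reference mass, the default when validating
printed tables) and full-precision mode; published tables rarely say which
of the two produced their error column, and the two can differ by 0.1 ppm
at 1 dp.

## Isotopologue simulation

`isotopologuePattern()` convolves the exact isotope distribution of every
atom (exponentiation-by-squaring of per-element distributions, absolute
pruning at 1e-15, so the total probability is conserved to better than
1e-9), then aggregates isotopologues into clusters with a greedy 0.01 Da
bin anchored at each cluster's first peak. A consequence worth knowing: in
a Br/Cl compound the halogen species (37Cl at +1.99705, 81Br at +1.99795)
form a sub-cluster separate from the 13C2 satellites (+2.00671, about
0.012 Da above the cluster anchor), so the reported A+2 centroid is the
halogen cluster itself. For the parent this yields 475.0100 (A+2) and
477.0073 (A+4), matching the published reference isotope ions 475.0101 and
477.0074 to within 0.2 mDa; each cluster also carries the m/z of its
single most abundant isotopologue (`species_mz`) for workflows that prefer
single-species reference ions. For one Br plus one Cl the A+2/A abundance
ratio is 0.3200 + 0.9728 ~ 1.29, the quantity the screening filter tests.

## Formula inference

`enumerateFormulas()` performs an exact residual-mass descent over
elements in decreasing mass order (Br, Cl, S, O, N, then C with H solved
from the residual), pruned by the attainable mass of the remaining
elements. Admissibility filters: ppm window (default 5), the nitrogen rule
applied to the neutral molecule (all 22 curated formulas pass under this
convention, which settled the neutral-vs-ion question in its favor),
integral RDBE in [0, 40], and optionally at least one Cl or Br -- the
halogen-retention assumption of targeted transformation-product screening,
on by default but switchable because fully dehalogenated products are
chemically plausible. Element bounds default to C 0-40, H 0-60, N 0-10,
O 0-12, S 0-2, Cl 0-2, Br 0-2, chosen to cover the curated table with
margin; they are configurable because the vendor software's internal
bounds are not published. Ranking is total and deterministic: |ppm|, then
isotope-fit score, then fewer heteroatoms, then the formula string.

`scoreIsotopeFit()` scores only the halogen-informative clusters (>= 25%
of base by default): weak 13C satellites carry no halogen evidence, and a
printed three-ion reference pattern (A, A+2, A+4) should score ~1 against
theory rather than be penalized for omitting them. Missing the base
cluster halves the remaining coverage-weighted score, which pushes a Br/Cl
candidate whose observed pattern lacks its A+2 below 0.5.

## Screening

The feature-level workflow mirrors vendor screening but is deterministic
and auditable; every stage returns a subset of its input and logs what it
removed (`screenAudit()`):

1. `subtractControl()` -- any-control-replicate semantics by default (a
   treated feature is eliminated if it matches any untreated sample within
   5 ppm and 0.1 min); a 10-fold enrichment mode is available.
2. `applyThresholds()` -- area >= 1e4 and S/N strictly > 10.
3. `halogenFilter()` -- requires an A+2 companion at 1.997 +- 0.006 Da
   (tight enough to exclude the 13C2 spacing of +2.007) with an A+2/A
   ratio within 30% of some combination of up to two Cl and two Br.
4. `matchSuspects()` -- 5 ppm, and 0.1 min when the suspect's retention
   time is known; retention time is what separates isobaric suspects
   (two curated compounds share calcd m/z 440.9861 at 10.27 vs 8.42 min).

Because no installed package provides vendor-independent feature
detection for this dialect, `detectFeatures()` implements a minimal
deterministic one: centroid peaks grouped across frames at 5 ppm, apex
intensity as feature area, and S/N defined as apex intensity over the
median intensity of other peaks within +-0.5 Da -- the definition is
stated because published methods rarely define S/N operationally.
`buildInclusionList()` deduplicates candidate masses at 25 ppm for
targeted MS2 acquisition.

## Annotation

Fragment evidence is data, not code: generic neutral losses
(anhydroglucose 162.0528, water, HCl, HBr, CO, HCN, methylamine) ship as
CSV and per-compound characteristic ions come from the curated table, so
the rule set is user-extensible and replaces opaque in-silico
fragmentation with transparent arithmetic (`matchFragments()` checks
|precursor - loss - observed| within 10 ppm). Confidence levels follow
the widely used identification-confidence scheme: level 1 needs a
reference standard; 2b, matched fragments plus prior literature; 3,
matched fragments with alternative structures possible (an input flag on
the suspect entry -- it encodes literature knowledge the software cannot
derive); 5, exact mass only. Levels 2a and 4 are representable but unused
by this rule set. `classifyPhase()` walks a curated pathway edge list:
any cleavage edge on the path means breakdown, a terminal conjugation
edge means phase II, anything else phase I; the packaged graph partitions
the 21 metabolites 11/6/4.

## Quantification

Calibration is an ordinary least-squares line over at least five standard
levels (0.8-800 ng/mL working range), unweighted by default with a 1/x
option since the underlying method does not state a weighting.
Fresh-weight conversion is
`extractConc * extractVolume / (sampleMass * concentrationFactor)`, and
recovery correction multiplies each sample by `100 / recovery%` of its
own isotope-labelled internal standard -- per sample, not batch mean,
because matrix effects differ by tissue and age. Detection limits use the
spiked-replicate approach: `LOD = t * S_s` with the one-tailed 99th
percentile Student quantile at n-1 degrees of freedom computed by
`qt()` (3.143 for seven injections, asserted to 3 dp in the tests) and
`LOQ = 3.3 * LOD` exactly. Matrix-specific published LOD/LOQ values are
deliberately not reproduced: the underlying replicate standard deviations
are not public, so only the formula layer is testable.

## The synthetic study generator

`simulateStudy()` generates the study design the analysis assumes:
control and treated groups (default 5 replicates), five matrices (xylem
sap, young and mature leaves, flowers, fruits) sampled at 7-14 day
intervals over 7-84 days after treatment. Its defaults are the study
conditions, not tuning knobs:

* Parent kinetics follow `kineticProfile()`,
  $A\,(t/\tau)\,e^{1-t/\tau}\,e^{-gt}$ -- a single-peak pulse with a
  growth-dilution tail. No functional form is published for such residue
  curves; this one has two interpretable parameters and reproduces the
  rise-then-decline pattern (xylem peaking at 7-14 DAT and ending below
  15% of peak; tissues peaking later at amplitudes ordered
  mature leaves > flowers > young leaves >> fruits).
* Metabolite signal fractions grow as
  $f(t) = f_{84}\,(t/84)^2$, keeping every metabolite-to-parent ratio
  below 10% through 28 DAT while letting the major products
  (ring-closure product 25%, N-demethylated product 30%, its glycoside
  18%) dominate late, as observed in practice.
* Per-matrix internal-standard recoveries default to the published means
  and spreads (92.6 +- 8.3, 81.0 +- 9.9, 105.7 +- 8.5, 74.1 +- 17.1,
  63.2 +- 14.5% for young leaves, mature leaves, flowers, green and red
  fruits); the drawn per-sample recovery multiplies all analyte and
  internal-standard areas of that sample, which is exactly the structure
  recovery correction inverts.
* Noise: between-plant lognormal variation of the true concentration
  (RSD 20%, the magnitude of published replicate spreads), per-peak
  lognormal noise of 5% (the repeatability of QC injections), 1 ppm m/z
  jitter, 0.02 min retention-time jitter. The per-sample recovery factor
  and the per-peak noise are deliberately separated: recovery-corrected
  concentrations and M/P ratios should cancel the former and feel only
  the latter.
* 50 matrix-interference features per tissue are planted identically in
  both groups (with carbon-only A+1 clusters), so control subtraction
  and the halogen filter each independently remove them.

What the generator does not emulate: chromatographic peak shapes,
profile-mode spectra, ion suppression beyond the scalar recovery factor,
retention-time drift between runs, and real matrix chemistry. Passing the
end-to-end tests therefore demonstrates the internal consistency of the
workflow's logic under its own assumptions, not performance on real raw
data.

## Numerical choices and scale

Tolerances live with the operations they gate: 5 ppm identification,
25 ppm inclusion lists, 0.1 min retention windows, area 1e4, S/N > 10,
isotope bin 0.01 Da, pattern prune 0.01% of base. Test and acceptance
runs use a scaled-down study -- two tissues, four sampling intervals,
three replicates, three seeds -- which keeps the full
simulate-screen-quantify loop under a minute while leaving every rate it
measures (detection of planted metabolites with M/P >= 1%, zero matrix
false positives, parent relative RMSE after recovery correction, M/P
recovery within three standard deviations of the configured sampling
noise) identical in definition to a full-size run. Degenerate inputs are
explicit: empty candidate sets are valid results, zero replicate variance
gives LOD 0 with a warning, a zero parent area flags the ratio cell
rather than dividing.

## Known limitations

* The element set is fixed to C/H/N/O/S/Cl/Br; no SMILES/InChI layer, no
  structure handling, no in-silico bond breaking.
* One adduct ([M+H]+, charge +1) -- the acquisition this workflow targets
  is positive-mode ESI.
* Published tables are transcriptions and inherit their own rounding: one
  curated row's printed calculated mass is internally inconsistent with
  its printed ppm error at the last decimal, and the fixture preserves the
  printed values rather than silently correcting them (the loader
  validates to 1e-4 Da for exactly this reason; the tests document the
  discrepancy).
* Retention-time matching assumes a stable method; there is no alignment
  across runs beyond the tolerance window.
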