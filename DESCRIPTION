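Package: haloscreen
Title: Halogen-Targeted Suspect Screening of Pesticide Transformation
    Products by LC-HRMS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for suspect screening and semi-quantification of
    halogenated pesticide transformation products in plant tissues by
    liquid chromatography high-resolution mass spectrometry. Provides
    exact-mass and molecular-formula arithmetic for the element set
    C/H/N/O/S/Cl/Br, chlorine/bromine isotopologue pattern simulation by
    exact convolution, formula enumeration under ppm, nitrogen-rule and
    ring-double-bond-equivalent constraints, a feature-level screening
    workflow (control-sample subtraction, intensity and signal-to-noise
    thresholds, halogen isotope filtering, suspect matching, inclusion
    lists), MS2 fragment matching with identification-confidence levels
    and transformation-phase classification, internal-standard recovery
    correction with Student-t based detection limits, metabolite-to-parent
    ratio kinetics, and a ground-truthed synthetic greenhouse-study
    generator. Ships a curated table of cyantraniliprole and 21 of its
    plant transformation products as a worked suspect list.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'chem.R'
    'annotate.R'
    'constants.R'
    'haloscreen-package.R'
    'infer.R'
    'io.R'
    'report.R'
    'quant.R'
    'screen.R'
    'simulate.R'
    'pipeline.R'
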