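Package: bnctdose
Title: Photon Isoeffective Dose Modelling for Boron Neutron Capture Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radiobiological modelling of mixed-field dosimetry in Boron
    Neutron Capture Therapy (BNCT) of glioblastoma. Implements the modified
    linear-quadratic (MLQ) cell-survival model with dual-kinetics
    (fast/slow) sub-lethal damage repair via Lea-Catcheside protraction
    factors, error-weighted fitting of clonogenic survival curves and
    bi-exponential DNA-repair (foci) kinetics, derivation of RBE and CBE
    factors at a survival endpoint, conversion of four-component BNCT dose
    distributions into photon-equivalent units (photon isoeffective dose
    and fixed-factor RBE-weighted dose), and DVH-based reporting with
    irradiation-time scaling to a normal-tissue prescription. Includes
    seeded synthetic-data generators (clonogenic assays with Poisson colony
    counts, foci-decay series, phantom dose-component grids) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'bnctdose-package.R'
    'core-models.R'
    'dosimetry.R'
    'fitting.R'
    'grids-reporting.R'
    'synthetic-data.R'
    'io.R'
    'pipeline.R'
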