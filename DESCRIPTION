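Package: viscomigration
Title: Modelling and Quantifying Viscosity-Enhanced Cell Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to model and quantify how elevated extracellular fluid
    viscosity enhances cell migration. Provides a filament-resolved
    stochastic simulator of lamellipodial actin network growth under
    membrane tension and a linear-viscous load, a steady-state solver for a
    one-dimensional two-phase (actin network plus cytosol) osmotic-engine
    model of confined migration in microchannels with regime-specific focal
    adhesion profiles and polarized ion fluxes, estimators for
    microscopy-derived records (cell tracks, segmentation stacks, contour
    series, fluorescence traces), and seeded synthetic-data generators with
    embedded ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
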