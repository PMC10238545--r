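Package: exstate
Title: Characterization of Sparsely Populated Protein Excited States by
    CPMG Relaxation Dispersion and Residual Dipolar Couplings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and solves the structure of a sparsely populated
    excited conformational state of a protein from solution NMR
    observables.  Implements exact two-site-exchange CPMG relaxation
    dispersion forward models with a numerical Bloch-McConnell oracle,
    single- and multi-temperature (Arrhenius-coupled) global dispersion
    fitting with multi-start error estimation, exchange lineshape
    simulation, Saupe alignment-tensor fitting of residual dipolar
    couplings by SVD with a sparsity-aware tensor-magnitude correction,
    population-weighted two-state (N = 2) ensemble refinement against
    multi-medium RDC sets with leave-one-set-out R-free cross-validation
    and a population-ratio grid search, structure superposition and RMSD
    utilities with region exclusion, and a synthetic-data generator that
    produces every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
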