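Package: hydrotherm
Title: Thermodynamics of Hydrophobic Association from Umbrella-Sampling Window Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs potentials of mean force (PMFs) for hydrophobic
    dimer association from umbrella-sampling window time series via the
    weighted histogram analysis method (WHAM), locates the contact minimum,
    desolvation maximum and solvent-separated minimum, and decomposes the
    temperature and ionic-strength dependence of the contact-minimum free
    energy into excess entropy, energy and heat capacity. A synthetic-data
    module generates biased reaction-coordinate series from a known model
    potential by Metropolis Monte Carlo, so every stage of the pipeline can
    be validated against ground truth without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'model-potential.R'
    'sampler.R'
    'study.R'
    'series-io.R'
    'histograms.R'
    'wham.R'
    'baseline.R'
    'bootstrap.R'
    'features.R'
    'thermo.R'
    'pipeline.R'
    'report-io.R'
    'show-methods.R'
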