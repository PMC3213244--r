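Package: enmodes
Title: Elastic Network Models, Normal Modes and Ensemble Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds elastic network models (Gaussian and anisotropic network
    models with cutoff, distance-weighted, nearest-neighbor and
    mixed-resolution spring schemes) from atomic structures, coarse-grained
    point models or electron density maps; solves their normal modes with
    dense or sparse eigensolvers; computes fluctuation, correlation,
    anisotropic displacement and collectivity analyses; and compares modes
    against principal components of structural ensembles using overlap,
    cumulative overlap and RMSIP metrics. Includes fixed-column PDB and
    MRC/CCP4 density map readers and writers, a synthetic fixture generator,
    and a command-line interface with molecular-viewer export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
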