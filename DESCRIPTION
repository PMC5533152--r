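Package: ratecorr
Title: Evolutionary Rate-Matrix Correlations on Samples of Time-Calibrated Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests for correlated evolution of two continuous traits under
    multivariate Brownian motion on phylogenies. Provides phylogenetic
    size-correction by generalized least squares, closed-form maximum-likelihood
    estimation of the 2x2 evolutionary rate matrix and its derived evolutionary
    correlation on each tree of a calibration sample, Akaike-weighted
    Fisher-transformed averaging of the per-tree correlations, stochastic
    tip-dating with "basic" and "equal" a-posteriori time-scaling of fossil
    cladograms, and a synthetic-data generator emulating every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
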