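Package: helitax
Title: Helical Chemotaxis Under Molecular Shot Noise with Gain Switching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-loop simulation of chemotaxis along helical swimming
    paths, as performed by sperm cells of marine invertebrates. Stochastic
    ligand binding (an inhomogeneous Poisson process) drives an adaptive
    signalling module that modulates path curvature and torsion, bending
    the helix towards the source of a radial chemoattractant field. The
    package provides the analytic coarse-grained theory linking the helix
    bending rate and the effective rotational diffusion of the centreline
    to the signal-to-noise ratio of gradient sensing; a finite-state
    Markov decision process over distance and orientation whose solution
    is the optimal switching strategy between low-gain and high-gain
    steering; and a cell-implementable decision rule acting on the
    internal signalling variables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
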