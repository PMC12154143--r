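Package: tdnmsRNN
Title: Curriculum Shaping and Attractor Dynamics in Recurrent Networks on a
    Temporal Non-Match-to-Sample Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a temporal delayed non-match-to-sample (tDNMS) Go/No-Go
    timing task, trains leaky recurrent rate networks on it by backpropagation
    through time under different shaping curricula, and analyses the trained
    networks as dynamical systems: trajectory tangling, fixed- and slow-point
    location with linear stability, limit-cycle detection, PCA state-space
    geometry with cross-projection and flow fields, and within- versus
    cross-context linear-discriminant decoding of elapsed trial time. A
    synthetic spike-train generator emulating temporally tuned cortical
    populations, together with the post-sorting preprocessing pipeline
    (binning, Gaussian smoothing, z-scoring, reliability-based unit selection
    and pseudo-population construction), makes the neural-data analyses
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
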