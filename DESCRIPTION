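Package: lgfret
Title: Single-Molecule FRET and Kinetic Analysis of Protein-Channel
    Lateral-Gate Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for single-molecule FRET studies of the
    SecYEG protein-conducting channel and its SecA motor ATPase. Provides
    photobleaching-based trace selection and acceptor-photobleaching FRET
    efficiency estimation, constrained multi-Gaussian global fitting of
    FRET-efficiency histograms with SVD-based model selection, Gillespie
    simulation of two-state (open/closed) channel kinetics with TIRF
    sampling emulation, ensemble tight-binding titration and stopped-flow
    exponential fits, and geometric distance metrics on coordinate files.
    A synthetic-data module generates every input the pipeline consumes
    under explicit seeds, so all stages are testable without experimental
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
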