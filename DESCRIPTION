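Package: scalesid
Title: Structural Identifiability of ODE Models by Scaling Invariance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tests local structural identifiability of ordinary
    differential equation models by searching for scaling symmetries of
    the parameters and latent (unobserved) state variables. Each
    right-hand side is decomposed into functionally independent additive
    summands; the invariance of every summand under log-scaling yields a
    homogeneous linear system over the rationals whose nullspace encodes
    the symmetry generators. Parameters and latent states whose scaling
    factor is forced to one are identifiable/observable; the remaining
    ones are classified into identifiable monomial groups
    (Buckingham-Pi style invariants). Symbolic verdicts are
    cross-validated numerically via forward sensitivity integration, the
    elasticity (relative sensitivity) matrix and finite scaling of
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
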