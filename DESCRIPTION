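Package: idpnse
Title: Structure and Dynamics of Disordered Proteins from Small-Angle
    Scattering and Neutron Spin-Echo
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for intrinsically disordered proteins in
    solution combining small-angle scattering and neutron spin-echo (NSE)
    spectroscopy.  Implements generalized Gaussian-coil form factors and
    Guinier analysis, Percus-Yevick hard-sphere structure factors, bead-model
    hydrodynamics (Kirkwood and Rotne-Prager-Yamakawa rigid-body diffusion),
    Zimm and Zimm-with-internal-friction (ZIF) intermediate scattering
    functions with global multi-q fitting, an anisotropic-network-model
    normal-mode description of internal motions with multipole-expansion
    dynamic form factors, and Brownian-oscillator friction extraction.
    A synthetic-data module generates coarse-grained chain ensembles and
    forward-modelled SAS/NSE data with known ground truth so that every
    stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    cluster
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
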