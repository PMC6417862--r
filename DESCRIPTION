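Package: actintread
Title: Global Treadmilling of Branched Actin Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of the dynamic steady state ("global treadmilling") of
    branched actin networks disassembled by ADF/Cofilin. Provides a 2D
    advection-diffusion-reaction solver for free and bound ADF/Cofilin around a
    growing network (local cofactor depletion), a stochastic lattice model of
    trailing-edge network fragmentation with a continuum mean-field
    approximation, a coupled-feedback solver for the equilibrium network length
    as a function of actin density, ADF/Cofilin concentration and network
    width, an elastic two-beam model of heterogeneous-network steering, a
    synthetic-data generator emulating kymographs, density profiles and
    equilibrium-length tables, and the associated inference procedures
    (binding-slope estimation, power-law exponent fitting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
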