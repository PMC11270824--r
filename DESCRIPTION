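Package: cg2des
Title: Coarse-Grained Two-Dimensional Electronic Spectroscopy of Segmented
    Frenkel-Exciton Aggregates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the third-order optical response (2DES) of large
    Frenkel-exciton aggregates by coarse-graining the system into weakly
    coupled segments.  Intra-segment optics is computed by nonadiabatic
    wavefunction propagation over stochastic Ornstein-Uhlenbeck site-energy
    trajectories (doorway and window response functions of the coherence
    times), while inter-segment excitation energy transfer during the
    waiting time is described by a detailed-balance-corrected rate matrix
    and its matrix-exponential transfer map.  Includes a brute-force full
    response oracle for small systems, isotropic orientational averaging,
    cross-peak kinetics and pump-probe anisotropy analyses, and fixture
    generators for dimer and LH2-like two-ring model systems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
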