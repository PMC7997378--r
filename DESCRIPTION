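Package: metasaxs
Title: Hybrid-Resolution SAXS-Restrained Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for determining conformational ensembles of flexible
    multidomain proteins restrained by small-angle X-ray scattering (SAXS)
    data at hybrid resolution. Provides a coarse-grained (Martini-style bead)
    Debye forward model for scattering intensities with analytical coordinate
    gradients, a Bayesian metainference restraint energy with Monte-Carlo
    sampled uncertainties and intensity scale, a desk-scale multi-replica
    Langevin sampler with well-tempered parallel-bias metadynamics, and a
    validation suite covering paramagnetic relaxation enhancement (PRE)
    back-calculation, Guinier and Kratky analysis, chi-square model-data
    agreement, conformational clustering, and free-energy surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
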