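Package: wolbanet
Title: Wolbachia Invasion Dynamics on Networks of Diffusively Coupled
    Mosquito Habitats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting whether a one-time release of
    Wolbachia-carrying Aedes aegypti mosquitoes achieves long-term fixation
    in one or more discrete habitats.  Implements a two-compartment
    carrier/non-carrier population model and a nine-compartment
    sex/life-stage model, extends both to N diffusively coupled habitats,
    and converts habitat geometry (pairwise distances, habitat radii) into
    migration coefficients via exponential and log-normal dispersal
    kernels.  Includes drivers for basin-of-attraction mapping, minimal
    release-size estimation, migration-parameter sweeps with bifurcation
    bracketing, and a one-dimensional reaction-diffusion adaptation that
    exhibits traveling invasion waves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
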