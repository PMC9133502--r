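Package: petkern
Title: Dynamic PET Kernel Reconstruction and lp-ntPET Kinetic Modeling Workbench
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis workbench for detecting transient
    neurotransmitter release in dynamic brain PET. Builds a 2D digital rat-brain
    phantom, generates region time activity curves from a time-varying-efflux
    reference-tissue model, projects them through an attenuated parallel-beam
    system model with Poisson counting noise, and reconstructs dynamic images by
    frame-independent MLEM, spatiotemporal kernel expectation-maximization, or
    MLEM with HYPR denoising. Fits the linear parametric neurotransmitter PET
    (lp-ntPET) model by exhaustive non-negative least squares over a
    gamma-variate basis-function library, computes activation response profiles
    and voxel-wise parametric maps, quantifies parameter uncertainty by
    approximate Bayesian computation, and drives seeded Monte-Carlo comparisons
    of the reconstruction arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    RNifti
Suggests:
    pracma,
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
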