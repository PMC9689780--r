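Package: braintomo
Title: Desk-Scale Microwave Brain Tomography with Deep-Learning Inversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-dimensional microwave brain imaging at desk scale:
    a procedural generator of nested-tissue dielectric brain phantoms with
    scaling, boundary deformation and spherical anomaly insertion; a
    volume-integral-equation forward scattering solver (Born and coupled-dipole
    modes) for a four-layer 60-dipole measurement array at 300 MHz; a
    full-convolutional encoder-decoder network that reconstructs per-voxel
    relative permittivity and conductivity volumes from aggregated scattered
    field measurements; a 2-D U-Net image-enhancement stage applied to axial
    slices; and model/data misfit evaluation with white-Gaussian-noise
    robustness sweeps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    RNifti,
    withr
Config/testthat/edition: 3
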