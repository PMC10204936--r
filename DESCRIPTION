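Package: fnirscnn
Title: Spatial-Temporal Convolutional Networks for High-Density
    Frequency-Domain fNIRS Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Probe-geometry-driven image construction and
    spatial-temporal convolutional classification of high-density
    frequency-domain functional near-infrared spectroscopy (FD-fNIRS)
    recordings for motor-task brain-computer interfaces.  Provides the
    checkerboard high-density optode geometry and nearest-neighbour
    channel enumeration, a frequency-domain photon-diffusion simulator
    of finger-opposition runs (haemodynamic response, systemic
    oscillations, distance-dependent noise, poor-quality channels), the
    full preprocessing chain (optical density, channel quality control,
    band-pass filtering, modified Beer-Lambert chromophore conversion,
    resampling, z-scoring, neighbour interpolation, windowing), three
    input representations (Block voxel images, Flat channel-by-time
    matrices, Source-by-Detector grids), mirror-flip label-swap
    augmentation, compiled 3D and 1D convolutional network classifiers,
    and the mixed-subjects / subject-independent evaluation protocol
    with macro-F1 scoring and two-way ANOVA model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    data.table
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
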