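Package: cellnematics
Title: Nematic Order, Collective Flow and Migration Statistics for Cell
    Monolayer Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies collective cellular alignment in microscopy time series
    of cell monolayers: structure-tensor orientation fields with coherency
    gating, the two-dimensional nematic orientation-order parameter and spatial
    disorder, nematic and velocity correlation lengths from spatial
    autocorrelation of axial angle fields, multipass FFT particle image
    velocimetry, nuclei detection and frame-to-frame track linking with
    density, speed and directional-bias statistics, half-integer topological
    defect detection by winding number with line-integral-convolution
    rendering, and the Watson-Wheeler test for angular homogeneity. Includes a
    synthetic-data generator (textured director fields, displaced image pairs,
    biased persistent random-walk nuclei movies, analytic defect fields) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
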