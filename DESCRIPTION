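Package: scratchfk
Title: Mechanistic Analysis of Scratch-Assay Images with the Fisher-Kolmogorov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates the contributions of cell motility and cell proliferation to
    scratch (wound-healing) assay closure by calibrating the Fisher-Kolmogorov
    reaction-diffusion model to live-imaging data. Provides a Canny-based
    leading-edge detection pipeline that measures the vacant scratch area over
    time, an implicit finite-difference solver for the one-dimensional
    Fisher-Kolmogorov equation (backward Euler, Picard linearisation, Thomas
    algorithm), and a three-stage sequential least-squares estimator for the
    carrying-capacity density K, the proliferation rate lambda and the cell
    diffusivity D. A fully seeded synthetic-assay generator (virtual microscopy,
    Poisson cell counts, noisy leading-edge series) supports parameter-recovery
    validation of the whole pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Rcpp,
    jsonlite,
    yaml,
    EBImage,
    tiff,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
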