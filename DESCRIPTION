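Package: musselcml
Title: Coupled Map Lattice Dynamics of Mussel-Algae Beds with
    Proportional-Differential Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Spatiotemporally discrete mussel-algae dynamics on a periodic
    coupled map lattice with self- and cross-diffusion and an optional
    proportional-differential feedback acting on the algae update.
    Provides the homogeneous map with its closed-form coexistence fixed
    point, Jacobian and stability classification, flip-bifurcation
    thresholds and the full centre-manifold normal form, discrete-Laplacian
    Turing mode analysis with threshold location, a fast lattice simulator,
    and diagnostics: bifurcation diagrams, maximum Lyapunov exponent
    sweeps, pattern-state counting and control-parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
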