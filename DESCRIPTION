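Package: cathflux
Title: Stage-Switched Radial Diffusion Modelling of Drug Release from
    Catheter Walls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Mechanistic modelling of antibiotic loading and release for
    drug-eluting urinary catheters. Solves Fick's second law on the annular
    catheter wall with stage-switched boundary conditions (concentrated
    loading bath, sealed rest stage, finite or sink delivery bath coupled
    through a reservoir ODE) using a mass-conservative finite-volume scheme.
    Includes cumulative-release analysis, loading/rest protocol sweeps,
    nonlinear least-squares estimation of diffusivity and partition
    coefficients from release profiles, a seeded synthetic-data generator,
    and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
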