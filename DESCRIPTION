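Package: spatsfs
Title: Site Frequency Spectra of Rare Deleterious Variants Under
    Geographically Concentrated Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytic and simulation tools for the site frequency spectrum
    (SFS) of rare alleles under negative selection in a two-dimensional
    continuous habitat sampled with a spatial kernel of finite breadth.
    Provides closed-form effective mutation and selection parameters for
    Gaussian and uniform sampling kernels on a torus, the negative-binomial
    finite-sample SFS and its summary statistics, a Gillespie simulator of
    the underlying spatial branching process with mutation influx, and a
    sampling-importance-resampling (SIR) pipeline for constructing
    spatially concentrated subsamples from cohorts of located individuals,
    including a synthetic-cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Matrix,
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
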