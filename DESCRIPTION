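Package: dcfsim
Title: Structured-Coalescent Simulation of the Doubly Conditioned
    Frequency Spectrum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates genealogies of chimpanzee, Neandertal, African and
    European samples under time-inhomogeneous structured demographic models
    (a spatial stepping-stone chain, a two-population ancient-structure
    model, and a clean-split model with an optional Neandertal admixture
    pulse), and computes the doubly conditioned frequency spectrum (dcfs)
    and Patterson's D statistic from genotype tables or directly from
    genealogical branch lengths.  Includes a parameter-sweep calibration
    layer that subsets demographic parameter combinations by their
    predicted D and ranks them by goodness of fit (R-squared) against an
    observed dcfs, plus synthetic-data generators for pseudo-observed
    spectra and toy genotype panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
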