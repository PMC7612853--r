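Package: rftec
Title: Expected Euler Characteristics of Gaussian Random Field Excursion Sets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates stationary unit-variance Gaussian random fields on
    rectangular lattices by buffered white-noise smoothing, computes Random
    Field Theory predictions of the expected Euler characteristic of
    excursion sets -- both Adler's original volume-only formula and the
    boundary-corrected Lipschitz-Killing-curvature expansion -- and runs
    Monte Carlo experiments comparing theory with the average number of
    suprathreshold clusters.  Includes periodic (torus) field generation
    together with the naive edge-labeling failure mode, which double-counts
    wrap-around clusters and distorts the smoothness dependence of observed
    cluster counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2,
    mvtnorm,
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
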