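Package: acotomo
Title: Ant-Colony Hyperparameter Tuning for Total-Variation CT Reconstruction
Version: 0.1.0
Authors@R: person("acotomo", "maintainers", email = "acotomo@example.org",
    role = c("aut", "cre"))
Description: Few-view X-ray computed tomography reconstruction with the
    adaptive-weighted projection-controlled steepest descent (AwPCSD)
    algorithm, together with an ant-colony-optimisation (ACO) tuner that
    selects its data-inconsistency tolerance and total-variation
    sub-iteration count automatically.  Includes matched Siddon-style
    forward and back projectors for parallel-, fan- and cone-beam
    geometries, SART, OS-SART and CGLS solvers, a piecewise-constant
    thorax-like digital phantom generator with mixed Poisson-Gaussian
    projection noise, image-quality metrics (correlation coefficient,
    universal quality index, relative error), a leave-one-angle-out
    cross-validation baseline, and a desk-scale experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
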