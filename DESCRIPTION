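Package: cbctscatter
Title: Iterative Monte Carlo Scatter Correction for Cone-Beam CT
Version: 0.1.0
Authors@R:
    person("CBCT", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Simulation and correction of X-ray scatter in cone-beam computed
    tomography (CBCT). Provides digital voxel phantoms with photon cross
    sections, a Monte Carlo photon transport engine with variance reduction
    (interaction splitting, Russian roulette, Woodcock delta tracking, forced
    detection), a deterministic Siddon ray tracer, FDK filtered backprojection
    with partial-arc weighting and a Shepp-Logan kernel, a projection-domain
    iterative scatter correction with relaxation and antiscatter-grid
    parameters, and image-quality metrics (CT-number error, RMSE, CNR) in the
    style of Catphan sensitometry analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
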