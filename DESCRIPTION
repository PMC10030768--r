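Package: bbanneal
Title: Protein Backbone Resonance Assignment by Bayesian Simulated Annealing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Automated assignment of protein backbone triple-resonance NMR
    crosspeaks to residues. Crosspeak lists from HSQC and CA/CB/CO-type
    triple-resonance experiments are assembled into amide-rooted spin
    systems, scored with a Bayesian pseudo-energy that combines a
    chi-square likelihood of observed versus predicted chemical shifts
    with an inverted-Gaussian adjacency term, and optimized by Metropolis
    simulated annealing under a specific-heat-guided cooling schedule.
    Final assignments are the curated majority-vote consensus of an
    ensemble of independent annealing runs. A synthetic triple-resonance
    data generator with depletion and artifact-injection transforms makes
    every stage testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    seqinr,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
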