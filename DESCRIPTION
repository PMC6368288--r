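Package: foodwebsens
Title: Perturbation Sensitivity Analysis for Age-Structured Marine Food Webs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, single-box simulator for age-structured marine food
    webs in the Atlantis tradition (availability-modified Holling grazing,
    linear plus density-dependent quadratic mortality, Beverton-Holt or
    constant per-adult recruitment, structural/reserve body weights), together
    with the machinery for local empirical sensitivity analysis: one-at-a-time
    parameter perturbation designs, extreme-value runs, impact-factor scoring
    of biomass responses, and classification of combined-perturbation
    responses as additive, synergistic or antagonistic. A synthetic food-web
    generator emulates the trophic structure of a Barents Sea-like system
    (zooplankton pools, wasp-waist pelagic fish, top predators) so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
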