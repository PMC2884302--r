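Package: abiplan
Title: Non-Iterative Aperture-Weight Optimization for Anatomy-Based IMRT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for aperture-based inverse planning (ABIP) in intensity
    modulated radiotherapy. Given a dose-influence matrix (dose per unit
    aperture weight at labelled sample points) and per-structure dose limits
    and penalties, the aperture weights are obtained in a single exact pass:
    the overdetermined linear dose system is reduced to its weighted
    normal-equations form and solved by Gaussian elimination with partial
    pivoting and back-substitution, with optional Tikhonov smoothing of the
    weights and a non-negativity clamp-and-refit pass. Includes a synthetic
    phantom simulator (parametric structures, anatomy-based beam's-eye-view
    apertures, seeded sample-point placement, primary-photon dose kernel)
    so plans can be generated and optimized without a commercial planning
    system, plus dose-volume histograms, plan-delivery metrics, plan
    comparison, penalty-trial replanning and aperture-count sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
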