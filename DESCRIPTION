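Package: roostfinder
Title: Diffusion-Based Estimation of Bat Roost Locations from Static
    Acoustic Detector Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Locates the likely position of a bat roost from the spatial
    pattern of echolocation calls recorded by an array of static acoustic
    detectors. Nightly dispersal from the roost is modelled as planar
    diffusion; integrating the dispersal density over each detector's
    circular footprint, and over the first 90 minutes after sunset, yields
    the expected proportion of calls at every detector for any candidate
    roost position. Scanning candidates over a landscape grid produces a
    normalized error surface whose minimum is the best point estimate and
    whose level sets rank the terrain into optimal search regions. Includes
    a fast algebraic approximation of the detection integral, a
    centre-of-calls baseline estimator, search-effort statistics, and a
    stochastic Brownian-agent simulator for generating synthetic surveys
    and validating the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
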