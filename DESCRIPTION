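Package: spotmatch
Title: Photo Re-Identification of Individual Animals from Spot Constellations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for re-identifying individual animals from photographs of
    their natural spot markings, developed around dark-spotted fish photographed
    on a light background. Provides classical (feature-engineered) and neural
    (encoder-decoder) segmentation of body and spot masks, conversion of spot
    masks into normalized (x, y, size) constellations, two triangle-invariant
    point-pattern matchers (a Groth-style voting matcher and a RANSAC
    similarity-transform matcher with a mask-overlap gate), chronological
    database ranking with open-set decisions and an ensemble rule,
    capture-history correction for tag loss, and a Bayesian Cormack-Jolly-Seber
    survival model. A synthetic-data module generates rendered fish images,
    perturbed constellation pairs with known correspondence, and capture
    histories with injected tag loss, so the whole pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
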