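Package: epiboly
Title: Mechanical Parameter Inference for Spreading Embryonic Tissue Explants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decipher the mechanics of embryonic tissue spreading from
    time-lapse kinematic data. Implements an Eulerian moving-boundary continuum
    model of explant spreading (level-set front tracking over a density
    diffusion equation with mass-limited logistic addition of visible
    material), a strain-mapping module that converts elastic-registration
    displacement fields into deformation gradients and density-ratio maps, and
    an approximate Bayesian computation (ABC) rejection sampler that fits the
    model to per-frame boundary contours and density-ratio maps, yielding
    posterior distributions for the mechanical parameters F/k (edge force over
    stiffness), k/b (effective diffusivity), alpha (visible material growth
    rate), and the unstressed tissue density. A synthetic-data generator
    emulates segmented time-lapse datasets with known ground truth for
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
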