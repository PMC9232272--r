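Package: octmoco
Title: Motion Compensation for Volumetric Corneal OCT by Higher-Order Surface Regression
Version: 0.1.0
Authors@R: person("OCT", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for removing axial and lateral motion artifacts from
    volumetric optical coherence tomography (OCT) scans of the cornea.
    Each B-scan is segmented (Gaussian smoothing, saturation-stripe
    removal, adaptive thresholding, connected-component selection,
    gradient refinement) and the anterior surface is fitted with a
    higher-order polynomial; per-frame lateral shifts are estimated by
    variance minimization between surface fits and axial motion is
    recovered from three slow-axis reference B-scans and interpolated
    with a quadratic across the fast axis.  The package also implements
    the Gaussian reference-placement accuracy theory used to optimize
    the spacing ratio of the reference planes, a seeded synthetic OCT
    acquisition simulator (speckled B-scans of corneal phantoms under
    sinusoidal or band-limited free-hand motion) for parameter-recovery
    testing, evaluation metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
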