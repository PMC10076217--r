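Package: panorf
Title: Panoramic Scene Statistics and Retina-Wide Receptive Field Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking the anisotropic statistics of panoramic natural
    scenes to the retina-wide organization of retinal ganglion cell (RGC)
    receptive fields (RFs). The package implements an efficient-coding model
    that optimizes spatial RFs under a sparsity-plus-locality cost across
    signal-to-noise conditions, a synthetic-scene generator with
    elevation-dependent power and a simulated horizon, a synthetic retina
    simulator producing deconvolved-like calcium responses to a shifting
    white-noise checkerboard, reverse-correlation RF estimation with
    population subtraction, constrained difference-of-Gaussians RF
    parametrization, and population-level trend statistics (binning,
    Kolmogorov-Smirnov tests, regression weights, Gaussian-mixture
    clustering of temporal RFs, tiling index, and saccade orientation
    statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mclust
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
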