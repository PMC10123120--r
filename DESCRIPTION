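Package: locusdyn
Title: Single-Particle Dynamics of Chromosomal Loci and Mobile Genetic
    Elements in Rod-Shaped Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for two-colour single-particle
    tracking of fluorescently labelled chromosomal loci and integrative and
    conjugative elements (ICEs) in rod-shaped bacteria. Provides an exact
    fractional Gaussian noise simulator (circulant embedding), alternative
    subdiffusion models (continuous-time random walks, obstructed diffusion),
    a whole-population generator with known behaviour-class mixtures, a
    diffraction-limited two-channel microscopy renderer, sub-pixel Gaussian
    spot localization in cell-frame coordinates, trajectory linking,
    anisotropic anomalous-diffusion statistics (time- and ensemble-averaged
    mean square displacement, power-law fits, velocity autocorrelation with
    self-similarity rescaling, ergodicity diagnostics, walk dimension), and
    behaviour classification of ICE trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    minpack.lm,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
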