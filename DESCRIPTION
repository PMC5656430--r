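Package: dualvsd
Title: Analysis Pipeline for Double-Sided Voltage-Sensitive-Dye Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pan-neuronal voltage-sensitive-dye (VSD) imaging of
    invertebrate ganglia recorded simultaneously from two surfaces. Provides a
    seeded synthetic generator of dual-view recordings with ground truth,
    sub-pixel rigid motion estimation and correction by a shifted-reference
    linear estimator, ROI trace extraction with local cubic (Savitzky-Golay)
    detrending and global background subtraction, multitaper coherence against
    a behavioral reference with analytic null thresholds and cross-animal
    involvement rules, partner-excluding leave-one-out stimulus decoding,
    packet-wise affine plus Gaussian-kernel registration of ROIs onto a
    canonical neuron map, and correlation-distance clustering with
    dorsoventrality indices and integration coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    signal,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
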