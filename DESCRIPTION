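Package: hemofus
Title: Multiparametric Ultrafast Ultrasound and Photoacoustic Brain Hemodynamics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computation chain for dual-modality functional ultrasound and
    multispectral photoacoustic imaging of brain hemodynamics. Provides
    spatiotemporal singular-value-decomposition clutter filtering of
    beamformed IQ movies, power-Doppler cerebral blood volume mapping,
    directional autocorrelation velocimetry for signed axial blood flow,
    energy-normalized non-negative least-squares spectral unmixing to
    oxy-/deoxy-hemoglobin, indocyanine green and oxygen saturation maps,
    microbubble ultrasound localization microscopy (sub-pixel localization,
    Hungarian track linking, super-resolved density/direction/speed maps),
    interleaved acquisition-sequence timing models, relative-change and
    cross-correlation hemodynamic analyses, and physics-informed synthetic
    data generators with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    pracma,
    tiff,
    png,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
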