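Package: herbspec
Title: Hyperspectral Imaging Chemometrics for Herbal Variety Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for discriminating botanical varieties
    from near-infrared hyperspectral images: ENVI-style cube input/output,
    white/dark reflectance calibration, Otsu threshold segmentation and
    region-of-interest spectral extraction, wavelength-edge cropping, wavelet
    (Daubechies) spectral denoising, principal component exploration, and
    three discriminant models (PLS-DA with leave-one-out component selection,
    radial-basis-function SVM with grid search, and a one-dimensional
    VGG-style convolutional network trained with Adam) evaluated with
    confusion matrices and macro precision/recall/F-score. A synthetic
    hypercube generator emulating the spectral structure of herbal bulb
    samples makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    e1071,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
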