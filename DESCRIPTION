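Package: jointmorph
Title: Mechanobiology of Embryonic Knee Joint Morphogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how muscle-contraction-generated
    biophysical stimuli pattern embryonic knee-joint morphogenesis. Provides a
    synthetic voxel-phantom generator for the developing chick knee (distal
    femur with condyles and intercondylar fossa, interzone, proximal
    tibiotarsus and fibula), a quasi-static linear poroelastic (Biot)
    plane-strain finite-element solver with Von Mises / principal stress,
    pore pressure and Darcy fluid-velocity post-processing, muscle load cases
    for dynamic flexion/extension versus rigid-paralysis regimes, 3D
    morphometric measurement of joint shape, cartilage outline extraction and
    rigid overlay, and the statistical stages (per-measurement one-way ANOVA
    with percent reduction, nested binomial mixed-effects proliferation
    model).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
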