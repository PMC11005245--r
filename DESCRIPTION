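Package: plimox
Title: Two-Photon Phosphorescence-Lifetime Oximetry and Capillary Flux Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pointwise two-photon phosphorescence lifetime
    imaging (2P-PLIM) oximetry in cortical microvasculature: mono-exponential
    fitting of time-correlated single-photon-counting (TCSPC) decay histograms
    with Grubbs rejection of motion-corrupted repetitions, Stern-Volmer
    conversion of lifetime to oxygen partial pressure, Hill-equation hemoglobin
    saturation, cortical-layer binning, depth-dependent oxygen extraction and
    coefficient-of-variation summaries, capillary red-blood-cell flux from
    valley counting in phosphorescence intensity traces, and percent-area
    immunofluorescence densitometry. Includes a forward model that simulates
    decays, flux traces, image stacks and full longitudinal cohorts with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    yaml,
    jsonlite,
    tiff,
    EBImage,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
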