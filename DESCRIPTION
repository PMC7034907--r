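Package: natronid
Title: Mineral Identification in Polychromatic Synchrotron MicroCT via
    X-Ray Attenuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative material identification for grayscale microCT
    volumes of mummified specimens. Computes theoretical mass and linear
    attenuation coefficients of arbitrary chemical compounds and hydration
    series from a bundled elemental cross-section table, simulates the
    detected spectrum of a filtered synchrotron bending-magnet beam through
    a scintillator detector (including beam-hardening diagnostics),
    calibrates the effective monochromatic energy of a polychromatic scan
    against a reference material such as cortical bone, and classifies
    dense inclusions by comparing measured attenuation against candidate
    minerals (the constituents of natron). Ships a synthetic phantom
    generator with ground-truth labels, 3D inclusion segmentation, and an
    end-to-end pipeline with TIFF/CSV/JSON interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
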