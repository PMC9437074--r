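Package: mpskin
Title: Multiphoton Multiparametric 3D Quantification of Human Skin
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying in vivo human skin structure from
    multichannel multiphoton z-stacks combining temporally binned
    two-photon excited fluorescence (2PEF-FLIM, four time channels) and
    second harmonic generation (SHG) imaging. The package segments the
    stratum corneum, living epidermis and dermis in 3D, extracts the
    dermal-epidermal junction (DEJ) as a regularized depth map, builds
    thickness-normalized epidermal and DEJ-shape-following dermal
    sublayers, and computes morphological metrics (layer thicknesses,
    normalized DEJ area), melanin 3D density and its z-epidermal
    distribution via Pseudo-FLIM slope analysis, dermal elastin and
    fibrillar collagen densities, the SHGto2PEF ratio, the 3D SAAID
    density index and the normalized imbrication index (ImbrN), together
    with descriptive and effect-size statistics (folded F test, Student
    t contrasts, Cohen's d with interpretation bands) for group
    comparisons. A synthetic skin phantom generator with full ground
    truth supports validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tiff, yaml, jsonlite, rlang
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
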