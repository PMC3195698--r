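Package: karyotex
Title: Nuclear Chromatin Texture Analysis for Immature Myeloid Precursors
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Karyometry and chromatin texture analysis of segmented cell
    nuclei from bone-marrow cytology. Computes geometric morphometry (area,
    perimeter, form factor, gray-level statistics), seven co-occurrence
    matrix texture features, and the Minkowski-Bouligand fractal dimension
    of the pseudo-3D intensity surface via the morphological blanket method,
    together with its goodness of fit. Aggregates per-nucleus features to
    patient level, runs paired and independent t-tests and repeated-measures
    analysis of variance across cell classes, and applies a four-outcome
    significance-pattern rule that places atypical immature myeloid
    precursors relative to myeloblasts and promyelocytes. Includes a fully
    seeded synthetic generator for nucleus images (fractional Brownian
    chromatin texture with controllable roughness and clumping) and patient
    cohorts, so the whole pipeline can be exercised without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
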