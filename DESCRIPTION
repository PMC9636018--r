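Package: spinmaps
Title: Spatial Autocorrelation-Preserving Null Models for Comparing Brain Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for statistically comparing scalar brain maps defined on
    spherical surface meshes or volumetric grids. Implements spatial
    permutation ("spin") null models on the sphere, parcellated spin variants
    with configurable medial-wall handling, variogram-matching generative
    surrogates, and Moran spectral randomization, together with resampling
    between mesh resolutions, parcellation utilities, and a surrogate-based
    map-to-map comparison workflow with false discovery rate correction.
    Includes seeded generators of Gaussian-random-field maps on icosphere
    meshes so every statistical property is testable without external data.
    Reads and writes GIFTI surface files and NIFTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    xml2,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
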