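Package: hyposeg
Title: Automated Segmentation and Volumetry of Small Brain Structures from T1-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end, fully seeded pipeline for convolutional segmentation of a
    small midline brain structure (modelled on the hypothalamus) and of the
    intracranial compartment from T1-weighted MR volumes, with volume
    quantification, intracranial-volume normalization, interquartile-range
    quality control, and group-level atrophy statistics. Ships a synthetic
    head-phantom generator with known ground-truth masks so every stage --
    preprocessing, contrast augmentation, encoder-decoder training, overlap and
    95th-percentile Hausdorff evaluation, Bland-Altman agreement, and
    normality-gated group tests -- is exercisable and testable without patient
    data. The 2-D encoder-decoder segmenter (U topology with configurable
    encoder block styles) and its training loop are implemented natively.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
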