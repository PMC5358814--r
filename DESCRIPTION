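Package: nesslerquant
Title: Morphological Quantification of Tissue Ammonia from Nessler-Stained Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies ammonia in brightfield micrographs of
    Nessler-stained tissue sections. The pipeline takes the value channel
    of the hue-saturation-value decomposition, inverts it, applies a fixed
    global threshold (default 0.7) and measures the fraction of image area
    occupied by stained precipitate. Per-sample replicate measurements are
    normalized to the mean of healthy-control samples and converted to an
    integer Ammonia Score (1-6) via a fixed bin table. Includes assay
    validation statistics (replicate and between-section coefficients of
    variation, Pearson method comparison against a paired colorimetric
    assay, between-group tests), a synthetic stained-section generator
    with pixel-exact ground truth, and a command-line interface for batch
    runs driven by a CSV sample manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
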