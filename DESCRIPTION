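Package: frostpheno
Title: RGB Image Phenotyping of Wheat Freezing Injury
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: High-throughput phenotyping of frost (freezing) damage in
    field-grown wheat from nadir-view RGB plot images. Segments green
    canopy from soil background with excess-green/excess-red color indices
    (ExG, ExR and their difference ExV) and Otsu's automatic threshold,
    extracts vegetation coverage, assigns a four-grade frost-damage score
    from coverage intervals, isolates yellow-white withered leaf tissue by
    HSI color-space thresholding, and batch-processes a full
    varieties-by-nitrogen-treatment field experiment into per-image,
    per-plot and per-treatment reports. A seeded synthetic canopy-scene
    generator with exact ground-truth masks makes every stage testable
    without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
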