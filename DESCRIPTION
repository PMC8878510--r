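Package: camquant
Title: Cell-Level Marker Quantification for CAM Xenograft Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification toolkit for human xenograft tissue grown on the
    chicken chorioallantoic membrane (CAM). Segments nuclei from the DAPI channel
    (background subtraction, percentile saturation, fixed thresholding and
    marker-controlled watershed splitting of touching nuclei), classifies nuclei
    into human, peripheral-chicken (CAM) and infiltrating-chicken classes from
    area, eccentricity and k-3 neighbour density with a linear classifier,
    measures per-cell nuclear and cytoplasmic mean fluorescence intensity,
    calls marker-positive cells, applies a stellate-cell elongation filter to
    fibrous markers, scores DAB immunohistochemistry by optical-density bins,
    and computes delta-delta-Cq relative expression with a dual fold-change and
    p-value cut-off. Includes a seeded synthetic-scene generator with ground
    truth so every stage is testable without raw tissue images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
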