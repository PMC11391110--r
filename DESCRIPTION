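Package: cobbcurve
Title: Automated Cobb-Angle Measurement from Spine Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies scoliotic spinal curvature on anteroposterior
    radiographs. Vertebral bounding boxes (from annotation files or a
    classical threshold-plus-Hough detector) are reduced to centers, a
    polynomial spinal midline is fitted by least squares, inflection
    points of the midline partition the spine into curve segments, and
    Cobb angles are computed from the midline tangents at segment
    boundaries. A rule-based subroutine classifies the curve pattern
    (thoracic, lumbar, thoracolumbar, combined) and grades severity.
    Includes a synthetic spine-phantom generator with analytically known
    ground-truth angles for end-to-end validation, image standardization
    and contrast enhancement utilities, and tools for comparing manual
    and automated angle measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    yaml,
    png,
    tiff,
    EBImage,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
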