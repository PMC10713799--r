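Package: trismometry
Title: Remote Photogrammetric Measurement of Trismus and Its Validation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring mouth opening (trismus) from mobile-phone
    photographs. Implements detection of a colored-disc fiducial reference
    frame and the derived pixel-to-millimetre calibration, manual grid and
    anatomical (incisor-width) calibration variants, the six clinical
    measurement scenarios that combine portrait/selfie photographs with the
    different calibration sources, and the agreement statistics used to
    validate such methods: the two-way random-effects intraclass correlation
    coefficient, Bland-Altman limits of agreement for repeated observations
    per subject (with an independent-observations sensitivity variant), and
    precision-based sample-size calculators. A synthetic scene renderer and a
    measurement-error simulator provide ground-truth data for end-to-end
    testing of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
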