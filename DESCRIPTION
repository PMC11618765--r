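Package: hsctools
Title: Boundary-Point Contour Accuracy Metrics for Radiotherapy Contour QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Hu similarity coefficient (HSC), a clinically
    oriented contour-accuracy metric defined as the fraction of
    final-contour boundary points left untouched during contour
    adjustment, together with volumetric Dice, surface-Dice and
    added-path-length comparators on stacks of closed planar polygons
    read from DICOM RT Structure Set files or a plain JSON dialect.
    Includes a synthetic bladder-like phantom generator, a deterministic
    simulator that constructs contour sets with prescribed (DSC, HSC)
    combinations by bisection on a radial shrink factor, and an analysis
    stage relating normalized contour-modification time to HSC and DSC
    via ordinary least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    pracma,
    withr
Config/testthat/edition: 3
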