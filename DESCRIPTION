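Package: explantr
Title: Quantitative Analysis of Axis Elongation in Zebrafish Blastoderm Explants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Morphometric and signaling-gradient quantification for zebrafish
    blastoderm explants and embryos undergoing axis elongation. Implements
    explant shape measurements (circularity, extension classification and
    length, geodesic half-width shape profiles, expression-domain morphology),
    a clone-dispersal statistic decomposed parallel and perpendicular to a
    time-varying extension axis, best-fit-ellipse cell-alignment metrics with
    paired nuclear signaling intensity readouts, nuclear pSmad5/pSmad2
    gradient profiling (cytoplasmic background subtraction, DAPI
    normalization, fixed-width binning with edge exclusion and control
    referencing, top-decile position, domain extent, graded/radial
    classification), a normality-gated statistical test harness, and a
    synthetic-data generator producing ground-truth-known fixtures for every
    input class so the full pipeline is testable without microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
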