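Package: windowquant
Title: Quantification of Intravital Window-Chamber Fluorescence Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable pipeline for quantifying longitudinal multichannel
    z-stack fluorescence images from dorsal skinfold window chambers:
    exposure normalization, focus stacking of z-stacks into all-in-focus
    images, background-relative thresholding and particle analysis of
    tumor-cell clusters (count, area, equivalent diameter, distance to the
    center of mass, area moment), and linear lymph/blood vessel density
    from traced or skeletonized centerlines. Includes a seeded synthetic
    scene generator that renders ground-truth multichannel z-stacks
    emulating collectively migrating tumor-cell clusters and tortuous
    vessels, used to validate every stage against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
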