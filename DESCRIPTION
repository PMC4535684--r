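Package: fishda
Title: Quantification of Differential Chromatin Accessibility from FISH Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies differential accessibility (DA) between homologous
    metaphase chromosome loci from fluorescence in situ hybridization (FISH)
    images. Probe signals are delineated with a gradient vector flow (GVF)
    active contour, background-corrected integrated intensities are reduced
    to a normalized inter-homolog difference statistic, and DA is called per
    locus with a two-proportion z-test, including pre/post-treatment
    comparisons. A companion module measures hybridized probe depth and
    volume per homolog from 3D structured-illumination z-stacks. A synthetic
    scene generator with analytic ground truth makes the whole pipeline
    testable without microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
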