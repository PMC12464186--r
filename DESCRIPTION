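Package: octalens
Title: Quantitative OCT-Angiography Perfusion Metrics and AS-OCT Lens
    Opacimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of en-face optical coherence
    tomography angiography (OCTA) images and anterior-segment OCT (AS-OCT)
    B-scans of the crystalline lens. Implements a multiscale Hessian
    (Frangi) vesselness filter, Otsu binarization, homotopic thinning,
    skeleton branch decomposition and nine macular perfusion metrics
    (vessel area density, diameter, perimeter and complexity indices,
    tortuosity, branchpoint/endpoint counts, total and average vessel
    length); AS-OCT lens densitometry via robust quartic surface fitting
    and an elliptical nuclear region of interest; longitudinal cohort
    statistics (repeated-measures ANOVA with Mauchly sphericity assessment
    and Greenhouse-Geisser correction, Pearson correlation screens); and
    synthetic-data generators with analytically known ground truth for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
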