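Package: breathmap
Title: Breath-Metabolome Fingerprinting from GC/MS Chromatograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis pipeline for exhaled-breath volatile-compound
    (breathomics) GC/MS data. Stage one detects chromatogram peaks by local
    maxima, topographic prominence, neighboring-local-minima integration
    bounds and trapezoidal areas, and confirms peaks against level-1/2
    approximations of a reverse-biorthogonal discrete wavelet transform.
    Stage two condenses each sample into a fixed ten-feature profile and
    clusters the cohort with spectral, k-means, DBSCAN and Ward agglomerative
    algorithms, selecting the number of clusters by the elbow criterion, then
    characterizes clusters by their unique compounds and clinical covariate
    summaries. Includes a synthetic-cohort generator with planted latent-class
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
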