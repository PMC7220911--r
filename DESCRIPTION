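Package: retscat
Title: Correlation and Layer Analysis for Co-Registered Retinal a/LCI and OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for depth-resolved angle-resolved low-coherence
    interferometry (a/LCI) of the retina co-registered with optical coherence
    tomography (OCT). Converts raw spectral-domain angular scans into
    depth-resolved angular scattering distributions, segments retinal layer
    boundaries (NFL, OPL, RPE) in OCT B-scans and maps them into a/LCI depth
    pixels, computes two-point spatial correlation of the scattered field by
    Fourier analysis, extracts log-log power-law slopes and the associated
    fractal dimension (FD = 3 - alpha), computes masked intensity-histogram
    statistics, and compares two-group cohorts with a balanced mixed
    repeated-measures ANOVA under compound symmetry. Includes a fully
    parameterized synthetic-data generator (angular planes with prescribed
    radial correlation power laws, interferometric raw scans, layered
    speckled B-scans, and two-group cohorts with compound-symmetric
    within-eye correlation) with complete ground-truth bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    car,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
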