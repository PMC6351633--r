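Package: scanqc
Title: Stability and Reproducibility Metrics for Mass Spectrometry Scan Series
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control for scan series acquired by direct-infusion and
    ambient-ionization mass spectrometry (ESI, DESI, NESI and related
    methods). Scans are binned onto a fixed m/z grid and compared with
    Pearson's r and the cosine measure; pairwise similarity matrices with
    measurement-group structure expose unstable scans and cross-sample
    differences. A moving-median smoother over the scan axis suppresses
    isolated artifact scans, and a threshold rule on scan-versus-reference
    cosine scores rejects artifacts before a consensus spectrum is formed.
    Includes a seeded synthetic-measurement generator with known ground
    truth, heatmap/TIC visualization, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    mzR,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
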