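Package: riboclock
Title: Circadian Translatome Analysis from Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing around-the-clock ribosome profiling
    experiments. Simulates paired footprint (RPF-seq) and RNA-seq alignments
    with known ground truth; converts footprints to A-site positions and
    computes quality-control statistics (read-length filtering, region
    occupancy, reading-frame preference, 3-nt periodicity); quantifies
    expression via upper-quartile normalisation, RPKM and translation
    efficiency; detects AUG-initiated upstream open reading frames and calls
    them translated from footprint frame preference; finds ribosome pause
    sites by trimean excess; fits 24-h harmonic (cosinor) rhythms with FDR
    control, classifies genes by mRNA/footprint rhythmicity, tests for
    time-dependent translation efficiency, and summarises peak phases with
    Rayleigh and Watson-Wheeler circular statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    MASS,
    limma,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
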