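Package: ilcprec
Title: Interlaboratory Precision Statistics for Compound-Specific
    Stable Carbon Isotope Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical evaluation of interlaboratory comparisons (ILC) of
    compound-specific delta-13C measurements, in the ISO 5725 tradition:
    Cochran, Grubbs and Double Grubbs outlier screening with a configurable
    iterative policy and a replayable audit trail; one-way random-effects
    variance decomposition into repeatability (s_r), between-laboratory (s_L)
    and reproducibility (s_R) standard deviations with relative SDs and the
    2.80-factor repeatability and reproducibility limits; measurement
    uncertainty from s_R; a deterministic synthetic ILC generator emulating a
    multi-laboratory honey-saccharide study design (laboratory bias plus
    replicate error, injectable outlier laboratories); and long/wide CSV
    interchange with per-analyte report rendering.  Ships the published
    precision summary of a 14-laboratory LC-IRMS honey saccharide comparison
    as a built-in reference table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
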