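Package: qamsvg
Title: Single-Marker Multi-Component Quantification (QAMS) for HPLC-PDA/ELSD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Quantitative Analysis of Multi-components by
    Single-marker (QAMS) calculus for HPLC peak-area data acquired on a
    photodiode-array detector (linear response) or an evaporative
    light-scattering detector (power-law response, linear in log10-log10
    coordinates). Provides calibration-curve fitting with linearity
    diagnostics and LOD/LOQ estimation, relative conversion factors by the
    slope-ratio and response-ratio constructions, indirect quantification of
    analytes from a single reference marker alongside the external-standard
    method, dry-weight content computation, and a validation battery
    (intra-day/inter-day/inter-laboratory RSD, spiked recovery, and the
    standard-method-difference comparison with a 5.00 percent agreement
    rule). A synthetic peak-table generator reproduces the statistical
    structure of a six-level geometric dilution design so that the whole
    pipeline is testable without instrument data. Ships with reference
    calibration parameters for five Panax vietnamensis saponins.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
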