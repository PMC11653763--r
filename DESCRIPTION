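Package: cardiotug
Title: Quantitative Analysis of Micropost-Suspended Cardiac Microtissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for engineered cardiac microtissues suspended on
    fibrous matrices between elastomeric microposts. Provides closed-form
    mechanics calibration (cantilever bending stiffness from a rod-probe
    deflection test; fiber-matrix elastic modulus from a transverse
    indentation test), twitch contractility metrics from post-deflection
    time series (force, stress, work, kinetics, beat frequency, fractional
    shortening, drug-response fold changes), calcium-transient statistics
    (beat rate, peak-to-peak irregularity, rise/decay times, FWHM, regional
    Pearson correlation), sarcomere and myofibril structural analysis
    (z-disc segmentation, proximity/orientation myofibril grouping, axial
    circular alignment statistics, areal density, matrix fiber fields), and
    3D adhesion/junction morphometrics (segmentation, volume, eccentricity,
    colocalization, per-cell normalization, subregion regression). Includes
    seeded synthetic-data generators with machine-readable ground truth for
    every pipeline input, so each stage is testable end-to-end without
    microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    EBImage,
    tiff,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
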