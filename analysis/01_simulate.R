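#!/usr/bin/env Rscript
# Build the synthetic microtissue bundle that the downstream analysis
# scripts (02-07) consume: post-deflection and calcium traces, a titin
# z-disc image, a 4-channel 3D adhesion stack, a calcium video, expression
# maps, and forward-generated mechanics calibration tables, all with
# ground truth in truth.json.

library(cardiotug)

bundle <- file.path("results", "bundle")
simulate_tissue_bundle(bundle, config = run_config(), seed = 1)

truth <- jsonlite::read_json(file.path(bundle, "truth.json"), simplifyVector = TRUE)
files <- list.files(bundle)
cat("Simulated tissue bundle in", bundle, "(", length(files), "files )\n")
cat("  twitch: amplitude", truth$twitch$amplitude * 1e6, "um at",
    truth$twitch$rate, "Hz\n")
cat("  calcium: peak dF/F0", truth$calcium$peak_dff,
    "| analytic rise", round(truth$calcium$rise_10_90, 4), "s\n")
cat("  sarcomere image:", truth$sarcomere$n_bands, "z-disc bands, coverage",
    round(truth$sarcomere$coverage, 4), ", dispersion",
    truth$sarcomere$dispersion_sd_deg, "deg\n")
cat("  adhesion stack: planted colocalization",
    truth$adhesions$planted_coloc_fraction, ",", truth$adhesions$n_nuclei,
    "nuclei\n")
cat("  mechanics: moduli", paste(truth$modulus_Pa / 1e3, collapse = " / "),
    "kPa; post stiffness", paste(round(truth$stiffness_N_per_m, 2),
    collapse = " / "), "N/m\n")
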