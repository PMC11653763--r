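#!/usr/bin/env Rscript
# Mechanics calibration: post bending stiffness from the rod-probe test
# and fiber-matrix elastic modulus from the transverse indentation test,
# from the bundle's calibration tables. Also verifies the forward-inverse
# round trip over the physiological stiffness range.

library(cardiotug)

bundle <- file.path("results", "bundle")
if (!dir.exists(bundle)) stop("run analysis/01_simulate.R first")

stiff <- read_stiffness_table(file.path(bundle, "stiffness.csv"))
mod <- read_modulus_table(file.path(bundle, "modulus.csv"))
write.csv(stiff, file.path("results", "bending_stiffness.csv"), row.names = FALSE)
write.csv(mod, file.path("results", "matrix_modulus.csv"), row.names = FALSE)

cat("Post bending stiffness (N/m):",
    paste(round(stiff$stiffness_N_per_m, 3), collapse = ", "), "\n")
cat("Matrix modulus (kPa):",
    paste(round(mod$modulus_Pa / 1e3, 2), collapse = ", "),
    "-- the soft / adult / diseased myocardium regimes\n")
cat("Matrix strain at these indentations:",
    paste(signif(mod$strain, 3), collapse = ", "), "\n")

# round-trip audit: forward-generated post forces must invert exactly
set.seed(1)
worst <- 0
for (i in 1:100) {
  L0 <- runif(1, 200e-6, 600e-6); dh <- runif(1, 20e-6, 100e-6)
  g <- indentation_geometry(L0, dh, runif(1, 0, 0.8 * dh^2 / L0))
  xs <- matrix_cross_section(runif(1, 1e-10, 5e-10))
  E <- 10^runif(1, log10(100), log10(1e5))
  fc <- gen_mechanics_case(E, g, xs)
  worst <- max(worst, abs(matrix_modulus(fc$post_force, g, xs) - E) / E)
}
cat("Forward-inverse round trip over 100 cases: max relative error",
    signif(worst, 3), "\n")
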