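#!/usr/bin/env Rscript
# 3D adhesion/junction morphometrics on the bundle stack: vinculin puncta
# volume and eccentricity, colocalization with titin and N-cadherin,
# per-cell normalization, the ICD:costamere ratio, and the subregion
# regression of the maturation marker on costameric vinculin.

library(cardiotug)

bundle <- file.path("results", "bundle")
truth <- jsonlite::read_json(file.path(bundle, "truth.json"), simplifyVector = TRUE)
chans <- c("vinculin", "titin", "ncadherin", "dapi")
stacks <- lapply(file.path(bundle, paste0("stack_", chans, ".tif")), read_stack)
names(stacks) <- chans
vs <- c(stacks$vinculin$pixel_size_um, stacks$vinculin$pixel_size_um,
        stacks$vinculin$z_step_um)

seg <- segment_objects_3d(stacks$vinculin$data, vs, min_volume_um3 = 0.05)
write.csv(seg$objects, file.path("results", "adhesion_objects.csv"),
          row.names = FALSE)
titin_mask <- stacks$titin$data > 0.5
ncad_mask <- stacks$ncadherin$data > 0.5
nn <- count_nuclei(stacks$dapi$data, vs)
cf <- coloc_fraction(seg, titin_mask, 0.25)
icd <- icd_costamere_ratio(seg, ncad_mask, titin_mask, 0.25)

cat(sprintf("%d vinculin puncta, mean volume %.3f um^3, mean eccentricity %.3f\n",
            nrow(seg$objects), mean(seg$objects$volume_um3),
            mean(seg$objects$eccentricity, na.rm = TRUE)))
cat(sprintf("Titin colocalization %.3f (planted %.2f); ICD:costamere ratio %.2f\n",
            cf, truth$adhesions$planted_coloc_fraction, icd))
cat(sprintf("%d nuclei (planted %d); vinculin volume per cell %.3f um^3\n",
            nn, truth$adhesions$n_nuclei,
            per_cell(sum(seg$objects$volume_um3), nn)))

mlc <- read_stack(file.path(bundle, "mlc2v.tif"))
cvn <- read_stack(file.path(bundle, "costameric_vinculin.tif"))
sr <- subregion_regression(mlc$data[, , 1], cvn$data[, , 1],
                           pixel_size_um = mlc$pixel_size_um, region_size_um = 20)
write.csv(sr$regions, file.path("results", "subregion_regression.csv"),
          row.names = FALSE)
cat(sprintf("Subregion regression over %d regions: slope %.3f (planted %.2f), R^2 %.3f\n",
            sr$n_regions, sr$slope, truth$regression$slope, sr$r_squared))
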