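# 3D puncta segmentation, colocalization, per-cell normalization, nuclei
# counting and the subregion regression.

voxel_grid <- function(d, vs) {
  list(X = array(rep(seq_len(d[2]) * vs[1], each = d[1]), d),
       Y = array(rep(seq_len(d[1]) * vs[2], times = d[2]), d),
       Z = array(rep(seq_len(d[3]) * vs[3], each = d[1] * d[2]), d))
}

test_that("segmentation recovers sphere volume and ellipsoid eccentricity", {
  d <- c(40, 40, 40); vs <- c(0.25, 0.25, 0.25)
  g <- voxel_grid(d, vs)
  sph <- ((g$X - 5)^2 + (g$Y - 5)^2 + (g$Z - 5)^2 <= 1) * 1
  seg <- segment_objects_3d(sph, vs, min_volume_um3 = 0.5)
  expect_equal(nrow(seg$objects), 1)
  expect_equal(seg$objects$volume_um3, 4 / 3 * pi, tolerance = 0.1)
  expect_lt(seg$objects$eccentricity, 0.2)
  # prolate ellipsoid with a = 2b = 2c: eccentricity sqrt(1 - 1/4)
  ell <- (((g$X - 5) / 2.5)^2 + ((g$Y - 5) / 1.25)^2 + ((g$Z - 5) / 1.25)^2 <= 1) * 1
  seg2 <- segment_objects_3d(ell, vs, min_volume_um3 = 0.5)
  expect_equal(seg2$objects$eccentricity, sqrt(3) / 2, tolerance = 0.05)
  # blank stack
  expect_equal(nrow(suppressWarnings(segment_objects_3d(array(0, d), vs))$objects), 0)
})

test_that("26-connected labeling separates diagonal-disjoint objects", {
  m <- array(FALSE, c(8, 8, 4))
  m[1:2, 1:2, 1] <- TRUE         # object 1
  m[6:7, 6:7, 4] <- TRUE         # object 2, nowhere adjacent
  m[3, 3, 2] <- TRUE             # diagonally touches object 1 -> same label
  lab <- label_components_3d(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[3, 3, 2], lab[1, 1, 1])
})

test_that("colocalization matches planted fractions and grows with dilation", {
  for (pf in c(0, 0.5, 1)) {
    st <- gen_adhesion_stack(planted_coloc_fraction = pf, seed = 3)
    seg <- segment_objects_3d(st$channels$vinculin, st$voxel_size_um, 0.05)
    cf <- coloc_fraction(seg, st$masks$titin, 0.25)
    expect_lt(abs(cf - pf), 0.05)
  }
  st <- gen_adhesion_stack(planted_coloc_fraction = 0.5, seed = 8)
  seg <- segment_objects_3d(st$channels$vinculin, st$voxel_size_um, 0.05)
  cfs <- vapply(c(0, 0.25, 0.5, 1), coloc_fraction, numeric(1),
                objects = seg, reference_mask = st$masks$titin)
  expect_true(all(diff(cfs) >= 0))
  # identical objects and reference: full overlap
  own <- seg$labels > 0
  expect_equal(coloc_fraction(seg, own, 0), 1)
})

test_that("per-cell normalization divides and commutes with aggregation", {
  expect_equal(per_cell(300, 10), 30)
  expect_equal(per_cell(0, 7), 0)
  expect_error(per_cell(10, 0), ">= 1")
  vols <- c(12, 30, 58)
  expect_equal(sum(per_cell(vols, 6)), per_cell(sum(vols), 6))
})

test_that("nucleus counting is exact for separated and touching nuclei", {
  st <- gen_adhesion_stack(n_nuclei = 6, seed = 5)
  expect_equal(count_nuclei(st$channels$dapi, st$voxel_size_um), 6)
  # two overlapping spheres of known centers split into two
  st2 <- gen_adhesion_stack(n_objects = 2, n_nuclei = 0,
                            nuclei_centers_um = rbind(c(5, 5, 4), c(7.6, 5, 4)),
                            seed = 2)
  expect_equal(count_nuclei(st2$channels$dapi, st2$voxel_size_um), 2)
  expect_warning(n0 <- count_nuclei(array(0, c(8, 8, 4)), c(0.25, 0.25, 0.5)),
                 "no nuclei")
  expect_equal(n0, 0L)
})

test_that("ICD:costamere ratio reflects planted voxel overlap", {
  st <- gen_adhesion_stack(n_objects = 12, planted_coloc_fraction = 1 / 3,
                           planted_icd_fraction = 2 / 3, seed = 4)
  seg <- segment_objects_3d(st$channels$vinculin, st$voxel_size_um, 0.05)
  r <- icd_costamere_ratio(seg, st$masks$ncadherin, st$masks$titin, 0.25)
  tv <- st$truth$objects
  planted <- sum(tv$volume_um3[tv$group == "icd"]) /
    sum(tv$volume_um3[tv$group == "coloc"])
  expect_equal(r, planted, tolerance = 0.1 * planted)
  # no costameric overlap at all
  st0 <- gen_adhesion_stack(planted_coloc_fraction = 0,
                            planted_icd_fraction = 0.5, seed = 6)
  seg0 <- segment_objects_3d(st0$channels$vinculin, st0$voxel_size_um, 0.05)
  expect_warning(r0 <- icd_costamere_ratio(seg0, st0$masks$ncadherin,
                                           st0$masks$titin, 0.25),
                 "zero costameric")
  expect_true(is.na(r0))
})

test_that("subregion regression reproduces planted linear relations", {
  set.seed(1)
  x <- matrix(runif(10000), 100, 100)
  sr <- suppressWarnings(
    subregion_regression(2 * x, x, pixel_size_um = 1, region_size_um = 10))
  expect_equal(sr$slope, 2)
  expect_equal(sr$r_squared, 1)
  expect_equal(sr$n_regions, 100)
  em <- gen_expression_maps(slope = 1.5, noise_sd = 0.05, seed = 2)
  sr2 <- subregion_regression(em$mlc2v, em$costameric_vinculin,
                              pixel_size_um = 1, region_size_um = 20)
  expect_equal(sr2$n_regions, 100)
  expect_lt(abs(sr2$slope - 1.5) / 1.5, 0.1)
  expect_gt(sr2$r_squared, 0.8)
  # slope/R^2 agree with the closed-form least squares on the region table
  xr <- sr2$regions$costameric_vinculin_intensity
  yr <- sr2$regions$mlc2v_intensity
  beta <- cov(xr, yr) / var(xr)
  expect_equal(sr2$slope, beta, tolerance = 1e-12)
  expect_equal(sr2$r_squared, cor(xr, yr)^2, tolerance = 1e-12)
  # degenerate designs
  expect_error(subregion_regression(x, matrix(1, 100, 100), pixel_size_um = 1,
                                    region_size_um = 10), "constant")
  expect_error(subregion_regression(x, x, pixel_size_um = 1,
                                    region_size_um = 100), "fewer than 5")
})

test_that("costameric map masks vinculin to titin-positive pixels", {
  v <- matrix(runif(64), 8, 8)
  m <- matrix(FALSE, 8, 8); m[1:4, ] <- TRUE
  cm <- costameric_vinculin_map(v, m)
  expect_equal(cm[1:4, ], v[1:4, ])
  expect_true(all(cm[5:8, ] == 0))
})
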