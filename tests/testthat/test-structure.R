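# Z-disc segmentation, myofibril grouping, circular alignment statistics,
# areal density, and matrix fiber fields.

test_that("segmentation recovers every band with the right orientation", {
  tc <- cbind(seq(20, 80, length.out = 5), seq(20, 80, length.out = 5))
  g <- gen_sarcomere_image(image_size_px = 512, pixel_size_um = 0.2,
                           track_centers_um = tc, track_orientations_deg = 0,
                           n_discs_per_track = 10, seed = 1)
  expect_equal(nrow(g$truth$bands), 50)
  zd <- segment_zdiscs(g$image, 0.2)
  expect_equal(nrow(zd), 50)
  # bands sit perpendicular to the 0-degree tracks: axial orientation +-90
  expect_true(all(cardiotug:::axial_diff(zd$orientation_deg, 90) < 2))
  # blank image: empty with warning
  expect_warning(z0 <- segment_zdiscs(matrix(0, 64, 64), 0.2), "empty")
  expect_equal(nrow(z0), 0)
})

test_that("an isotropic blob is flagged orientation-indeterminate", {
  img <- matrix(0, 64, 64)
  img[28:36, 28:36] <- 1
  zd <- segment_zdiscs(img, 0.2, background_sigma_um = NULL)
  expect_equal(nrow(zd), 1)
  expect_true(zd$indeterminate[1])
})

test_that("grouping chains collinear discs and respects gap/angle limits", {
  zd <- data.frame(id = 1:10, x_um = 2 * (0:9), y_um = 0,
                   area_um2 = 0.5, orientation_deg = 90, indeterminate = FALSE)
  mf <- group_myofibrils(zd, max_gap_um = 3)
  expect_equal(nrow(mf), 1)
  expect_equal(mf$n_discs, 10)
  expect_equal(mf$n_sarcomeres, 9)
  expect_equal(mf$length_um, 18)
  expect_equal(cardiotug:::axial_diff(mf$mean_orientation_deg, 0), 0, tolerance = 1e-6)
  # too-small gap threshold: every chain dissolves below the minimum length
  expect_equal(nrow(group_myofibrils(zd, max_gap_um = 1)), 0)
  # two parallel rows stay distinct
  zd2 <- rbind(zd, transform(zd, id = id + 10, y_um = 10))
  mf2 <- group_myofibrils(zd2, max_gap_um = 3)
  expect_equal(nrow(mf2), 2)
  expect_equal(sort(vapply(mf2$zdisc_ids, length, integer(1))), c(10L, 10L))
})

test_that("grouping is independent of z-disc input order", {
  g <- gen_sarcomere_image(orientation_dispersion_sd_deg = 20, seed = 5)
  zd <- segment_zdiscs(g$image, 0.2)
  mf_a <- group_myofibrils(zd)
  set.seed(1)
  mf_b <- group_myofibrils(zd[sample(nrow(zd)), ])
  expect_equal(mf_a$zdisc_ids, mf_b$zdisc_ids)
  expect_equal(mf_a$mean_orientation_deg, mf_b$mean_orientation_deg)
})

test_that("alignment deviation matches the doubled-angle closed form", {
  expect_equal(alignment_deviation(rep(30, 5)), 0)
  # equal mass at -20 and +20 degrees: 0.5*sqrt(-2 ln cos(40 deg)) in degrees
  closed <- 0.5 * sqrt(-2 * log(cos(40 * pi / 180))) * 180 / pi
  expect_equal(alignment_deviation(c(-20, 20)), closed, tolerance = 1e-9)
  # invariant under rotation and axial relabeling
  th <- c(-35, -10, 0, 12, 40)
  expect_equal(alignment_deviation(th + 57), alignment_deviation(th), tolerance = 1e-9)
  expect_equal(alignment_deviation(th + 180), alignment_deviation(th), tolerance = 1e-9)
  # large-sample wrapped normal recovers its SD
  set.seed(2)
  draws <- cardiotug:::wrap_axial(rnorm(10000, 40, 15))
  expect_equal(alignment_deviation(draws), 15, tolerance = 0.5)
  expect_warning(ad1 <- alignment_deviation(42), "fewer than 2")
  expect_true(is.na(ad1))
})

test_that("dispersion is recovered from generated images across seeds", {
  for (sig in c(5, 30)) {
    ests <- vapply(1:5, function(s) {
      g <- gen_sarcomere_image(orientation_dispersion_sd_deg = sig, seed = s)
      alignment_deviation(group_myofibrils(segment_zdiscs(g$image, 0.2)))
    }, numeric(1))
    expect_lt(abs(mean(ests) - sig) / sig, 0.15)
  }
})

test_that("alignment deviation is rotation invariant on images", {
  g <- gen_sarcomere_image(orientation_dispersion_sd_deg = 15, seed = 4)
  base <- alignment_deviation(group_myofibrils(segment_zdiscs(g$image, 0.2)))
  for (phi in c(15, 90)) {
    rot <- as.matrix(EBImage::rotate(EBImage::Image(g$image), phi, bg.col = 0)@.Data)
    ad <- alignment_deviation(group_myofibrils(segment_zdiscs(rot, 0.2)))
    expect_lt(abs(ad - base), 1)
  }
})

test_that("areal density matches planted coverage and ignores intensity gain", {
  g <- gen_sarcomere_image(coverage_fraction = 0.2, allow_overlap = TRUE, seed = 1)
  d <- myofibril_density(g$image)
  expect_lt(abs(d - g$truth$coverage), 0.02)
  expect_equal(myofibril_density(g$image * 4.2), d)
  expect_equal(myofibril_density(g$image * 0.3), d)
  # saturated and blank masks
  expect_equal(myofibril_density(matrix(c(0, 1), 32, 32)), 0.5)
  expect_error(myofibril_density(g$image, matrix(FALSE, 256, 256)), "empty")
})

test_that("fiber field reads stripe orientation, density and dispersion", {
  img <- matrix(0, 128, 128)
  for (r in 1:128) img[r, ] <- 0.5 + 0.5 * sin(2 * pi * r / 8)
  ff <- fiber_field(img, pixel_size_um = 0.5, node_spacing_um = 16, window_um = 12)
  good <- !ff$absent
  expect_true(any(good))
  expect_true(all(cardiotug:::axial_diff(ff$orientation_deg[good], 0) < 2))
  expect_true(all(ff$dispersion_deg[good] < 3))
  # isotropic noise: dispersion far above the aligned case
  set.seed(1)
  ffn <- fiber_field(matrix(runif(128 * 128), 128, 128), 0.5, 16, 12)
  expect_gt(mean(ffn$dispersion_deg[!ffn$absent]), 30)
  # blank image: all nodes absent
  ffb <- fiber_field(matrix(0, 64, 64), 0.5, 16, 12)
  expect_true(all(ffb$absent))
})
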