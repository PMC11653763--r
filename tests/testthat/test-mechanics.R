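# Cantilever and fiber-matrix calibration physics.

tungsten <- rod_probe(400e9, 50e-6, 10e-3)

test_that("rod force matches hand evaluation and is linear in deflection", {
  # F = 3 d E I / L^3 with I = pi r^4 / 4, evaluated by hand:
  expect_equal(rod_force(tungsten, 6e-6), 3.534292e-5, tolerance = 1e-6)
  expect_identical(rod_force(tungsten, 0), 0)
  d <- c(1e-6, 3e-6, 7.5e-6)
  expect_equal(rod_force(tungsten, 2 * d), 2 * rod_force(tungsten, d))
  expect_error(rod_probe(-1, 50e-6, 10e-3), "positive")
})

test_that("bending stiffness divides rod force by post displacement", {
  m <- stiffness_measurement(10e-6, 4e-6)
  expect_equal(bending_stiffness(tungsten, m), 3.534292e-5 / 4e-6,
               tolerance = 1e-6)
  # force-free contact: rod undeflected
  expect_equal(bending_stiffness(tungsten, stiffness_measurement(10e-6, 10e-6)), 0)
  expect_error(bending_stiffness(tungsten, stiffness_measurement(10e-6, 0)),
               "degenerate")
  expect_error(stiffness_measurement(5e-6, 10e-6), "manipulator")
})

test_that("stretched half-length follows the indentation geometry", {
  expect_equal(stretched_half_length(indentation_geometry(400e-6, 0, 0)), 200e-6)
  g <- indentation_geometry(400e-6, 50e-6, 2e-6)
  expect_equal(stretched_half_length(g), 204.2156e-6, tolerance = 1e-6)
  # 45-degree symmetry case
  g45 <- indentation_geometry(400e-6, 200e-6, 0)
  expect_equal(stretched_half_length(g45), 200e-6 * sqrt(2))
  expect_error(indentation_geometry(400e-6, 10e-6, 250e-6), "initial_span/2")
})

test_that("matrix tension resolves the post force along the stretched fiber", {
  g <- indentation_geometry(400e-6, 50e-6, 2e-6)
  expect_equal(matrix_tension(0.82e-6, g), 0.82e-6 * 204.2156 / 198,
               tolerance = 1e-6)
  # in-plane limit: no indentation means tension equals post force
  g0 <- indentation_geometry(400e-6, 0, 2e-6)
  expect_equal(matrix_tension(1.3e-6, g0), 1.3e-6)
  expect_identical(matrix_tension(0, g), 0)
  expect_gte(matrix_tension(0.82e-6, g), 0.82e-6)
})

test_that("matrix modulus chains stress over strain and guards zero strain", {
  g <- indentation_geometry(400e-6, 50e-6, 2e-6)
  xs <- matrix_cross_section(2.5e-10)
  E <- matrix_modulus(0.82e-6, g, xs)
  expect_equal(matrix_strain(g), 0.021079, tolerance = 1e-4)
  expect_equal(E, 160.5e3, tolerance = 1e-3)
  expect_error(matrix_modulus(1e-6, indentation_geometry(400e-6, 0, 0), xs),
               "zero strain")
})

test_that("forward-generated cases round-trip to the target modulus", {
  g <- indentation_geometry(400e-6, 50e-6, 2e-6)
  xs <- matrix_cross_section(2.5e-10)
  for (E in c(0.68e3, 10.1e3, 17.4e3, 5e4)) {
    fc <- gen_mechanics_case(E, g, xs)
    expect_equal(matrix_modulus(fc$post_force, g, xs) / E, 1, tolerance = 1e-12)
  }
  expect_error(gen_mechanics_case(1e3, indentation_geometry(1e-4, 0, 0), xs),
               "zero-strain")
})

test_that("modulus is monotone in post force; half-length monotone in depth", {
  g <- indentation_geometry(400e-6, 50e-6, 2e-6)
  xs <- matrix_cross_section(2.5e-10)
  forces <- seq(0.1e-6, 2e-6, length.out = 8)
  E <- vapply(forces, matrix_modulus, numeric(1), geom = g, xsec = xs)
  expect_true(all(diff(E) > 0))
  dh <- seq(0, 100e-6, length.out = 9)
  lf <- vapply(dh, function(h) {
    stretched_half_length(indentation_geometry(400e-6, h, 2e-6))
  }, numeric(1))
  expect_true(all(diff(lf) > 0))
})

test_that("calibration tables compute stiffness and modulus per row", {
  sp <- file.path(tempdir(), "stiff.csv")
  write.csv(data.frame(probe_E_Pa = 400e9, probe_r_m = 50e-6, probe_L_m = 10e-3,
                       manip_disp_m = c(10e-6, 12e-6), post_disp_m = c(4e-6, 5e-6)),
            sp, row.names = FALSE)
  tab <- read_stiffness_table(sp)
  expect_equal(tab$stiffness_N_per_m[1], 8.8357, tolerance = 1e-4)
  mp <- file.path(tempdir(), "mod.csv")
  g <- indentation_geometry(400e-6, 50e-6, 2e-6)
  xs <- matrix_cross_section(2.5e-10)
  f <- gen_mechanics_case(10.1e3, g, xs)$post_force
  write.csv(data.frame(L0_m = 400e-6, dh_m = 50e-6, delta_m = 2e-6,
                       post_force_N = f, area_m2 = 2.5e-10), mp, row.names = FALSE)
  tab2 <- read_modulus_table(mp)
  expect_equal(tab2$modulus_Pa, 10.1e3, tolerance = 1e-9)
  expect_error(read_stiffness_table(mp), "missing columns")
})
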