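# Generator contracts: determinism, truth-record fidelity, guards.

test_that("every generator is bit-identical under a fixed seed", {
  expect_identical(gen_twitch_trace(seed = 11), gen_twitch_trace(seed = 11))
  expect_identical(gen_calcium_trace(seed = 11, noise_sd = 1),
                   gen_calcium_trace(seed = 11, noise_sd = 1))
  expect_identical(gen_sarcomere_image(seed = 11), gen_sarcomere_image(seed = 11))
  expect_identical(gen_adhesion_stack(seed = 11), gen_adhesion_stack(seed = 11))
  expect_identical(gen_post_video(seed = 11, noise_sd = 0.01),
                   gen_post_video(seed = 11, noise_sd = 0.01))
  # different seeds differ
  expect_false(identical(gen_twitch_trace(seed = 1)$trace$left_deflection,
                         gen_twitch_trace(seed = 2)$trace$left_deflection))
})

test_that("noiseless periodic twitch trains have exact beat structure", {
  r <- gen_twitch_trace(amplitude = 1e-5, rate = 1, interval_jitter_sd = 0,
                        noise_sd_fraction = 0, duration = 30, seed = 1)
  expect_equal(length(r$truth$beat_times), 29)   # beats from 1 s to 29 s
  expect_true(all(abs(r$truth$intervals - 1) < 1e-12))
  expect_error(gen_twitch_trace(rate = 0.1, duration = 5), "rate \\* duration")
})

test_that("jittered intervals realize the requested spread", {
  sds <- vapply(1:10, function(s) {
    sd(gen_twitch_trace(rate = 1, interval_jitter_sd = 0.15, duration = 62,
                        seed = s)$truth$intervals)
  }, numeric(1))
  expect_lt(abs(mean(sds) - 0.15) / 0.15, 0.2)
})

test_that("calcium truth carries analytic kinetics of the kernel", {
  r <- gen_calcium_trace(baseline = 100, peak_dff = 0.5, rate = 0.5,
                         duration = 30, noise_sd = 0, seed = 1)
  # raw peak of an isolated transient reaches baseline * (1 + peak_dff)
  expect_equal(max(r$trace$intensity), 150, tolerance = 0.5)
  # crossing times satisfy the kernel equation g(t) = level
  k <- function(t) cardiotug:::twitch_kernel(t, r$truth$rise_tau, r$truth$decay_tau)
  cr <- cardiotug:::kernel_crossings(r$truth$rise_tau, r$truth$decay_tau)
  expect_equal(k(cr$peak_time), 1, tolerance = 1e-9)
  expect_gt(cr$decay_90_10, cr$rise_10_90)  # decay slower than rise
})

test_that("sarcomere generator reports exact band truth when non-overlapping", {
  g <- gen_sarcomere_image(seed = 2)
  expect_equal(g$truth$coverage, mean(g$image > 0.5), tolerance = 0.01)
  expect_gt(nrow(g$truth$bands), 0)
  # dispersion zero collapses every track to the mean orientation
  g0 <- gen_sarcomere_image(orientation_dispersion_sd_deg = 0,
                            mean_orientation_deg = 25, seed = 3)
  expect_true(all(abs(g0$truth$track_orientations_deg - 25) < 1e-9))
  expect_error(gen_sarcomere_image(coverage_fraction = 0.9), "infeasible")
})

test_that("adhesion generator plants exact object groups and nuclei", {
  st <- gen_adhesion_stack(planted_coloc_fraction = 0.5, n_objects = 12,
                           n_nuclei = 6, seed = 1)
  tv <- st$truth$objects
  expect_equal(nrow(tv), 12)
  expect_equal(sum(tv$group == "coloc"), 6)
  expect_equal(st$truth$n_nuclei, 6)
  # planted objects sit inside their reference masks
  expect_true(all(st$channels$vinculin[st$masks$titin] %in% c(0, 1)))
  expect_error(gen_adhesion_stack(n_objects = 500), "overcrowded")
})
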