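# Twitch detection and contractility metrics on generated traces.

soft_post <- post_spec(0.41, "soft")
geom <- tissue_geometry(400e-6, 50e-6, 15e-6)

test_that("twitch detection finds every generated beat and nothing else", {
  r <- gen_twitch_trace(amplitude = 1e-5, rate = 1, interval_jitter_sd = 0,
                        noise_sd_fraction = 0, duration = 30, seed = 1)
  ev <- detect_twitches(r$trace)
  expect_equal(nrow(ev), length(r$truth$beat_times))
  # flat trace: no events, with a warning
  t <- seq(0, 4, 1 / 65)
  expect_warning(ev0 <- detect_twitches(deflection_trace(t, rep(0, length(t)))),
                 "no twitches")
  expect_equal(nrow(ev0), 0)
  # single half-sine twitch: one event peaking at the apex sample
  y <- ifelse(t >= 1 & t <= 1.5, 5e-6 * sin(pi * (t - 1) / 0.5), 0)
  ev1 <- detect_twitches(deflection_trace(t, y))
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$peak_time, t[which.max(y)], tolerance = 2 / 65)
  expect_error(detect_twitches(deflection_trace(t[t < 1], y[t < 1])), "2 s")
})

test_that("metrics match hand arithmetic for force, stress, work, shortening", {
  r <- gen_twitch_trace(amplitude = 1e-5, rate = 1, noise_sd_fraction = 0,
                        duration = 60, seed = 2)
  tm <- twitch_metrics(r$trace, soft_post, geom)
  expect_equal(tm$max_force, 0.41 * 1e-5, tolerance = 0.01)      # k * delta
  expect_equal(tm$max_stress, tm$max_force / (50e-6 * 15e-6))    # F / (w t)
  expect_identical(tm$work_per_twitch, 0.41 * tm$delta_max^2)    # k * delta^2
  expect_equal(tm$fractional_shortening, 2 * tm$delta_max / 400e-6)
  expect_equal(tm$frequency, 1, tolerance = 0.01)
})

test_that("force scales linearly and work quadratically with the trace", {
  r <- gen_twitch_trace(amplitude = 5e-6, rate = 0.8, duration = 60, seed = 3)
  tr <- r$trace
  scaled <- deflection_trace(tr$time, 3 * tr$left_deflection,
                             3 * tr$right_deflection)
  m1 <- twitch_metrics(tr, soft_post)
  m3 <- twitch_metrics(scaled, soft_post)
  expect_equal(m3$max_force, 3 * m1$max_force)
  expect_equal(m3$work_per_twitch, 9 * m1$work_per_twitch)
})

test_that("contraction plus relaxation duration stays within the beat period", {
  for (s in 1:5) {
    f <- c(0.5, 0.8, 1.2, 1.6, 2)[s]
    r <- gen_twitch_trace(rate = f, duration = 30, seed = s)
    tm <- twitch_metrics(r$trace, soft_post)
    expect_lte(tm$contraction_duration + tm$relaxation_duration, 1 / f)
    expect_gt(tm$contraction_duration, 0)
    expect_gt(tm$relaxation_duration, 0)
  }
})

test_that("diastolic length subtracts twice the tonic deflection", {
  r <- gen_twitch_trace(amplitude = 5e-6, rate = 1, noise_sd_fraction = 0,
                        duration = 30, seed = 4)
  tr <- r$trace
  # relaxed tissue: zero baseline
  expect_equal(diastolic_length(tr, 400e-6), 400e-6, tolerance = 1e-2)
  # 5 um tonic deflection per post
  tonic <- deflection_trace(tr$time, tr$left_deflection + 5e-6,
                            tr$right_deflection + 5e-6)
  expect_equal(diastolic_length(tonic, 400e-6), 390e-6, tolerance = 1e-2)
  expect_error(diastolic_length(tonic, 9e-6), "non-positive")
})

test_that("drug response reports per-metric fold changes with guards", {
  r1 <- gen_twitch_trace(amplitude = 4e-6, rate = 1, duration = 30, seed = 5)
  r2 <- gen_twitch_trace(amplitude = 6e-6, rate = 1.5, duration = 30, seed = 6)
  pre <- twitch_metrics(r1$trace, soft_post)
  post <- twitch_metrics(r2$trace, soft_post)
  dr <- drug_response(pre, post)
  expect_equal(dr$force_fold, post$max_force / pre$max_force)
  expect_equal(dr$frequency_fold, 1.5, tolerance = 0.02)
  expect_equal(drug_response(pre, pre)$force_fold, 1)
  broken <- pre; broken$max_force <- 0
  expect_warning(dr0 <- drug_response(broken, post), "undefined")
  expect_true(is.na(dr0$force_fold))
})

test_that("post tracking recovers sub-pixel sinusoidal displacement", {
  v <- gen_post_video(amplitude_px = 8, noise_sd = 0.02, seed = 3)
  tmpl <- list(list(x0 = 12, y0 = 16, w = 17, h = 17, toward = c(1, 0)),
               list(x0 = 69, y0 = 16, w = 17, h = 17, toward = c(-1, 0)))
  tr <- track_posts(v$video, tmpl, pixel_size_um = 1, sampling_rate = 65)
  err_px <- max(abs(tr$left_deflection * 1e6 - v$truth$displacement_px))
  expect_lt(err_px, 0.25)
  # static video tracks to an all-zero trace
  v0 <- gen_post_video(amplitude_px = 0, seed = 1)
  tr0 <- track_posts(v0$video, tmpl[1], pixel_size_um = 1, sampling_rate = 65)
  expect_equal(max(abs(tr0$left_deflection)), 0)
  big <- list(list(x0 = 1, y0 = 1, w = 500, h = 500, toward = c(1, 0)))
  expect_error(track_posts(v0$video, big, 1, 65), "larger than frame")
})
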