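# Calcium transient normalization, kinetics, rhythm and regional coherence.

test_that("dF/F0 normalization is exact on simple traces", {
  t <- seq(0, 10, 1 / 65)
  # constant trace normalizes to all zeros
  tr <- normalize_dff(calcium_trace(t, rep(100, length(t))))
  expect_equal(max(abs(tr$normalized)), 0)
  # baseline 100 with an isolated peak at 150 gives peak dF/F0 = 0.5
  f <- rep(100, length(t)); f[t >= 5 & t <= 5.2] <- 150
  tr2 <- normalize_dff(calcium_trace(t, f))
  expect_equal(max(tr2$normalized), 0.5, tolerance = 1e-9)
  expect_lte(abs(stats::median(tr2$normalized)), 0.02)
  expect_error(calcium_trace(t, rep(-1, length(t))), ">= 0")
})

test_that("triangular pulse yields exact FWHM and threshold times", {
  t <- seq(0, 6, 1 / 65)
  y <- pmax(0, 1 - abs(t - 3) / 0.5)   # 0 -> 1 over 0.5 s, back over 0.5 s
  fm <- flux_metrics(calcium_trace(t, 100 * (1 + 0.5 * y)))
  expect_equal(fm$fwhm, 0.5)
  expect_equal(fm$rise_time, 0.4)
  expect_equal(fm$decay_time, 0.4)
})

test_that("irregularity is the sample SD of inter-peak intervals", {
  # peaks planted exactly on the sample grid at 1.0, 2.0, 3.2, 4.0 s
  t <- seq(0, 5, 1 / 65)
  y <- rep(0, length(t))
  for (pt in c(1.0, 2.0, 3.2, 4.0)) y <- pmax(y, pmax(0, 1 - abs(t - pt) / 0.15))
  fm <- flux_metrics(calcium_trace(t, 100 * (1 + y)))
  expect_equal(fm$n_peaks, 4)
  expect_equal(fm$irregularity, sd(c(1.0, 1.2, 0.8)), tolerance = 1e-9)
  expect_equal(fm$beats_per_minute, 60, tolerance = 1e-9)
})

test_that("rhythm metrics recover generated jittered trains", {
  for (s in 1:5) {
    r <- gen_calcium_trace(rate = 1, interval_jitter_sd = 0.15, duration = 62,
                           noise_sd = 0.5, seed = s)
    fm <- flux_metrics(r$trace)
    bpm_true <- 60 / mean(r$truth$intervals)
    expect_equal(fm$beats_per_minute, bpm_true, tolerance = 0.01)
    expect_equal(fm$irregularity, sd(r$truth$intervals), tolerance = 0.2 * sd(r$truth$intervals))
  }
})

test_that("kinetics are recovered within a frame of the kernel crossings", {
  frame <- 1 / 65
  for (td in c(0.05, 0.2, 0.5)) {
    r <- gen_calcium_trace(rise_tau = td / 4, decay_tau = td, rate = 0.25,
                           duration = 40, noise_sd = 0, seed = 3)
    fm <- flux_metrics(r$trace)
    expect_lt(abs(fm$rise_time - r$truth$rise_10_90), frame)
    expect_lt(abs(fm$decay_time - r$truth$decay_90_10), frame)
    expect_lt(abs(fm$fwhm - r$truth$fwhm), frame)
  }
})

test_that("empty and sparse traces degrade gracefully", {
  t <- seq(0, 5, 1 / 65)
  expect_warning(fm <- flux_metrics(calcium_trace(t, rep(100, length(t)))),
                 "no peaks")
  expect_true(is.na(fm$beats_per_minute))
  # two peaks: kinetics yes, irregularity no
  y <- pmax(pmax(0, 1 - abs(t - 1) / 0.2), pmax(0, 1 - abs(t - 3) / 0.2))
  expect_warning(fm2 <- flux_metrics(calcium_trace(t, 100 * (1 + y))),
                 "fewer than 3")
  expect_false(is.na(fm2$rise_time))
  expect_true(is.na(fm2$irregularity))
})

test_that("regional correlation is exact for uniform and structured videos", {
  cv <- gen_calcium_video(mode = "uniform", n_frames = 130, seed = 1)
  expect_equal(regional_correlation(cv$video, cv$mask)$mean_pearson, 1)
  # alternating sinusoid and its negation across the 16 tiles
  t <- (0:199) / 65
  w <- sin(2 * pi * t)
  mask <- matrix(TRUE, 8, 32)
  lab <- cardiotug:::tile_mask(mask, 16)
  vid <- array(0, c(8, 32, 200))
  for (r in 1:16) {
    sel <- lab == r
    for (f in 1:200) {
      fr <- vid[, , f]; fr[sel] <- (if (r %% 2) 1 else -1) * w[f]; vid[, , f] <- fr
    }
  }
  # 56 same-sign pairs at +1, 64 cross pairs at -1 -> mean -1/15
  expect_equal(regional_correlation(vid, mask)$mean_pearson, -1 / 15)
  # independent noise regions decorrelate
  cvn <- gen_calcium_video(mode = "independent", n_frames = 1000, seed = 2)
  expect_lt(abs(regional_correlation(cvn$video, cvn$mask)$mean_pearson), 0.05)
})

test_that("tile_mask partitions the mask into equal-area regions", {
  mask <- matrix(TRUE, 20, 40)
  lab <- cardiotug:::tile_mask(mask, 16)
  counts <- table(lab[lab > 0])
  expect_equal(length(counts), 16)
  expect_lte(diff(range(counts)), 0.1 * mean(counts))
  expect_equal(sum(counts), sum(mask))
})
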