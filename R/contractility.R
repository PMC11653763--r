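#' Post-deflection time series
#'
#' Container for a twitch-contraction recording: the deflection of one or
#' both post tips toward the tissue center on a uniform time grid. Where
#' only one post was tracked the other is assumed to mirror it (symmetric
#' tissue). The per-post deflection used by all downstream metrics is the
#' mean of the two channels.
#'
#' @param time Time stamps in seconds, strictly increasing and uniform.
#' @param left_deflection Left post tip deflection (m), toward center.
#' @param right_deflection Optional right post deflection (m); defaults to
#'   mirroring the left.
#' @param sampling_rate Sampling rate in Hz; inferred from `time` if `NULL`.
#' @return An object of class `deflection_trace`.
#' @export
deflection_trace <- function(time, left_deflection, right_deflection = NULL,
                             sampling_rate = NULL) {
  stopifnot(is.numeric(time), is.numeric(left_deflection))
  if (length(time) != length(left_deflection)) {
    stop("deflection_trace: time and left_deflection lengths differ")
  }
  dt <- diff(time)
  if (any(dt <= 0)) stop("deflection_trace: time must be strictly increasing")
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    stop("deflection_trace: time grid must be uniform")
  }
  fs <- if (is.null(sampling_rate)) 1 / stats::median(dt) else sampling_rate
  if (abs(fs * stats::median(dt) - 1) > 1e-3) {
    stop("deflection_trace: sampling_rate inconsistent with time grid")
  }
  if (is.null(right_deflection)) right_deflection <- left_deflection
  stopifnot(length(right_deflection) == length(time))
  structure(
    list(time = time, left_deflection = left_deflection,
         right_deflection = right_deflection, sampling_rate = fs),
    class = "deflection_trace"
  )
}

# Per-post deflection (mean of the two channels).
trace_deflection <- function(trace) {
  (trace$left_deflection + trace$right_deflection) / 2
}

# Light Savitzky-Golay smoothing used before peak finding / amplitude
# measurement; falls back to the raw signal for very short traces.
smooth_trace <- function(x, n = 9L, p = 3L) {
  n <- as.integer(n)
  if (n %% 2L == 0L) n <- n + 1L
  if (length(x) <= n) return(x)
  signal::sgolayfilt(x, p = p, n = n)
}

# Beat-averaged twitch amplitude. Segments of the raw per-post deflection
# around each detected peak are averaged; with enough beats, extremum
# LOCATIONS are taken from the average of one half of the beats and the
# VALUES read off the other half's average (roles swapped and averaged),
# which removes the selection bias that picking the max/min of a noisy
# average would introduce. The peak value gets a 3-point parabolic
# sub-sample refinement; the trough is the mean over the four samples up
# to the trough location (its decay side, which is flat).
beat_averaged_amplitude <- function(y0, pk, median_interval) {
  n <- length(y0)
  w <- max(3L, round(0.45 * median_interval))
  keep <- pk[pk - w >= 1 & pk + w <= n]
  if (!length(keep)) return(NA_real_)
  segmat <- t(vapply(keep, function(p) y0[(p - w):(p + w)], numeric(2 * w + 1)))
  m <- ncol(segmat)
  measure <- function(loc_avg, val_avg) {
    im <- which.max(loc_avg); imn <- which.min(loc_avg)
    pkv <- val_avg[im]
    if (im > 1 && im < m) {
      den <- val_avg[im - 1] - 2 * val_avg[im] + val_avg[im + 1]
      if (den < 0) {
        pkv <- val_avg[im] - (val_avg[im - 1] - val_avg[im + 1])^2 / (8 * den)
      }
    }
    tro <- mean(val_avg[max(1, imn - 3):imn])
    pkv - tro
  }
  if (nrow(segmat) >= 6) {
    odd <- colMeans(segmat[seq(1, nrow(segmat), 2), , drop = FALSE])
    even <- colMeans(segmat[seq(2, nrow(segmat), 2), , drop = FALSE])
    (measure(odd, even) + measure(even, odd)) / 2
  } else {
    avg <- colMeans(segmat)
    measure(avg, avg)
  }
}

#' Tissue geometry
#'
#' @param diastolic_length Post-tip to post-tip tissue length at rest (m).
#' @param width Tissue width (m).
#' @param thickness Tissue thickness (m); suspended fiber tissues are thin,
#'   around 15 um.
#' @return An object of class `tissue_geometry` with derived `cross_section`.
#' @export
tissue_geometry <- function(diastolic_length, width, thickness = 15e-6) {
  stopifnot(diastolic_length > 0, width > 0, thickness > 0)
  structure(
    list(diastolic_length = diastolic_length, width = width,
         thickness = thickness, cross_section = width * thickness),
    class = "tissue_geometry"
  )
}

#' Detect twitch events in a deflection trace
#'
#' Peaks of the (lightly smoothed) per-post deflection above a rolling
#' 10th-percentile baseline, kept when their height exceeds
#' `min_prominence_fraction` of the tallest peak. Onset and offset are the
#' samples where the deflection crosses 10% of the twitch amplitude on
#' either side of the peak.
#'
#' @param trace A [deflection_trace()].
#' @param min_prominence_fraction Fraction of the largest peak height a
#'   peak must exceed (default 0.2).
#' @param baseline_window_s Rolling-baseline window in seconds (default 5).
#' @param min_separation_s Minimum peak-to-peak separation in seconds.
#' @return A data.frame with columns `peak`, `onset`, `offset` (sample
#'   indices), `peak_time`, `amplitude` (m, above local baseline). Zero rows
#'   (with a warning) when no twitch is found.
#' @export
detect_twitches <- function(trace, min_prominence_fraction = 0.2,
                            baseline_window_s = 5, min_separation_s = 0.2) {
  stopifnot(inherits(trace, "deflection_trace"))
  if (diff(range(trace$time)) < 2) stop("detect_twitches: trace must be at least 2 s long")
  y <- smooth_trace(trace_deflection(trace))
  fs <- trace$sampling_rate
  base <- rolling_baseline(y, round(baseline_window_s * fs))
  pk <- find_peaks(y, baseline = base, min_prominence_fraction = min_prominence_fraction,
                   min_separation = max(1L, round(min_separation_s * fs)))
  # merge double-detections on a twitch shoulder: drop the smaller of any
  # pair closer than 45% of the median beat interval
  if (length(pk) >= 3) repeat {
    iv <- diff(pk)
    bad <- which(iv < 0.45 * stats::median(iv))
    if (!length(bad)) break
    i <- bad[1]
    drop <- if (y[pk[i]] - base[pk[i]] < y[pk[i + 1]] - base[pk[i + 1]]) i else i + 1
    pk <- pk[-drop]
  }
  if (!length(pk)) {
    warning("detect_twitches: no twitches detected")
    return(data.frame(peak = integer(0), onset = integer(0), offset = integer(0),
                      peak_time = numeric(0), amplitude = numeric(0)))
  }
  amp <- y[pk] - base[pk]
  onset <- offset <- integer(length(pk))
  for (k in seq_along(pk)) {
    lev <- base[pk[k]] + 0.1 * amp[k]
    i <- pk[k]
    while (i > 1 && y[i - 1] > lev) i <- i - 1
    onset[k] <- i
    j <- pk[k]
    while (j < length(y) && y[j + 1] > lev) j <- j + 1
    offset[k] <- j
  }
  data.frame(peak = pk, onset = onset, offset = offset,
             peak_time = trace$time[pk], amplitude = amp)
}

#' Twitch contractility metrics
#'
#' Converts a deflection trace into per-tissue twitch metrics using the
#' post spring constant: maximum force \eqn{F = k \delta_{max}} (per post),
#' stress \eqn{F / (w t)}, work per twitch \eqn{W = k \delta_{max}^2}
#' (peak elastic energy stored in BOTH posts: half k delta^2 per post,
#' doubled), contraction/relaxation velocities (extrema of the
#' Savitzky-Golay smoothed deflection derivative, 5-frame window),
#' contraction/relaxation durations (10% amplitude crossings to/from the
#' peak), beat frequency, and fractional shortening
#' \eqn{2\delta_{max}/L_{diastolic}}. Per-twitch quantities are averaged
#' across detected twitches.
#'
#' @param trace A [deflection_trace()].
#' @param post A [post_spec()].
#' @param geom Optional [tissue_geometry()]; without it, stress, work-based
#'   normalization and fractional shortening are reported `NA`.
#' @param ... Passed to [detect_twitches()].
#' @return An object of class `twitch_metrics` (a named list).
#' @export
twitch_metrics <- function(trace, post, geom = NULL, ...) {
  stopifnot(inherits(trace, "deflection_trace"), inherits(post, "post_spec"))
  ev <- detect_twitches(trace, ...)
  if (nrow(ev) == 0) stop("twitch_metrics: no twitches detected")
  k <- post$bending_stiffness
  fs <- trace$sampling_rate
  y0 <- trace_deflection(trace)
  y <- smooth_trace(y0)
  med_iv <- if (nrow(ev) >= 2) stats::median(diff(ev$peak)) else round(fs)
  delta_max <- beat_averaged_amplitude(y0, ev$peak, med_iv)
  if (!is.finite(delta_max)) delta_max <- mean(ev$amplitude)

  # velocities from the 5-frame smoothed derivative of per-post deflection
  dy <- signal::sgolayfilt(trace_deflection(trace), p = 2, n = 5, m = 1, ts = 1 / fs)
  contraction_velocity <- max(dy)
  relaxation_velocity <- max(-dy)

  # interpolated 10%-crossing durations around each peak
  base <- rolling_baseline(y, round(5 * fs))
  cdur <- rdur <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    lev <- base[ev$peak[i]] + 0.1 * ev$amplitude[i]
    t_on <- crossing_time(trace$time, y, lev, ev$peak[i], -1L)
    t_off <- crossing_time(trace$time, y, lev, ev$peak[i], +1L)
    cdur[i] <- ev$peak_time[i] - t_on
    rdur[i] <- t_off - ev$peak_time[i]
  }
  frequency <- if (nrow(ev) >= 2) 1 / mean(diff(ev$peak_time)) else NA_real_

  out <- list(
    max_force = k * delta_max,
    max_stress = NA_real_,
    work_per_twitch = k * delta_max^2,
    contraction_velocity = contraction_velocity,
    relaxation_velocity = relaxation_velocity,
    contraction_duration = mean(cdur, na.rm = TRUE),
    relaxation_duration = mean(rdur, na.rm = TRUE),
    frequency = frequency,
    fractional_shortening = NA_real_,
    diastolic_length = NA_real_,
    delta_max = delta_max,
    n_twitches = nrow(ev)
  )
  if (!is.null(geom)) {
    stopifnot(inherits(geom, "tissue_geometry"))
    out$max_stress <- out$max_force / geom$cross_section
    out$fractional_shortening <- 2 * delta_max / geom$diastolic_length
    out$diastolic_length <- geom$diastolic_length
  }
  structure(out, class = "twitch_metrics")
}

#' @export
print.twitch_metrics <- function(x, ...) {
  cat("Twitch metrics (", x$n_twitches, " twitches)\n", sep = "")
  cat(sprintf("  max force        %.3g uN (per post)\n", x$max_force * 1e6))
  if (is.finite(x$max_stress)) cat(sprintf("  max stress       %.3g kPa\n", x$max_stress / 1e3))
  cat(sprintf("  work per twitch  %.3g pJ\n", x$work_per_twitch * 1e12))
  cat(sprintf("  frequency        %.3g Hz\n", x$frequency))
  cat(sprintf("  contraction/relaxation velocity  %.3g / %.3g um/s\n",
              x$contraction_velocity * 1e6, x$relaxation_velocity * 1e6))
  cat(sprintf("  contraction/relaxation duration  %.3g / %.3g s\n",
              x$contraction_duration, x$relaxation_duration))
  if (is.finite(x$fractional_shortening)) {
    cat(sprintf("  fractional shortening  %.3g\n", x$fractional_shortening))
  }
  invisible(x)
}

#' Diastolic tissue length from tonic post deflection
#'
#' The resting (inter-twitch) tissue length: the unloaded post-to-post span
#' minus twice the tonic baseline deflection of a post. A tissue under
#' increased diastolic tension pulls the posts inward and shortens.
#'
#' @param trace A [deflection_trace()].
#' @param resting_span Unloaded post-to-post span (m).
#' @return Diastolic length (m).
#' @export
diastolic_length <- function(trace, resting_span) {
  stopifnot(inherits(trace, "deflection_trace"), resting_span > 0)
  y <- trace_deflection(trace)
  base <- rolling_baseline(y, round(5 * trace$sampling_rate))
  # sustained activity leaves no inter-twitch plateau to estimate from
  amp <- max(y) - min(y)
  if (amp > 0 && stats::median(base) > min(y) + 0.8 * amp) {
    stop("diastolic_length: no identifiable inter-twitch baseline (tonic contraction?)")
  }
  tonic <- stats::median(base)
  len <- resting_span - 2 * tonic
  if (len <= 0) stop("diastolic_length: computed length non-positive; inconsistent inputs")
  len
}

#' Drug-response fold changes
#'
#' Fold change in contractile force and beat frequency between paired
#' recordings of the same tissue (e.g. before and after a beta-adrenergic
#' agonist).
#'
#' @param pre,post [twitch_metrics()] from the same tissue.
#' @return A list with `force_fold` and `frequency_fold`; a metric with a
#'   zero or missing pre value is returned `NA` with a warning.
#' @export
drug_response <- function(pre, post) {
  stopifnot(inherits(pre, "twitch_metrics"), inherits(post, "twitch_metrics"))
  fold1 <- function(a, b, what) {
    if (!is.finite(a) || a == 0) {
      warning("drug_response: pre ", what, " is zero or missing; fold undefined")
      return(NA_real_)
    }
    b / a
  }
  list(force_fold = fold1(pre$max_force, post$max_force, "force"),
       frequency_fold = fold1(pre$frequency, post$frequency, "frequency"))
}

#' Track post tips in a time-lapse video
#'
#' Sub-pixel template tracking: for each post, a template region from the
#' first frame is matched in every frame by normalized cross-correlation
#' over a local search window, with quadratic interpolation of the
#' correlation peak for sub-pixel displacement. Displacement is projected
#' onto the unit vector toward the tissue center to give deflection.
#'
#' @param video 3D numeric array `[row, col, frame]`.
#' @param templates List of one or two template regions, each a list with
#'   `x0`, `y0` (1-based top-left corner), `w`, `h` (pixels) and `toward`
#'   (length-2 unit-ish vector `(dx, dy)` pointing toward the tissue
#'   center; normalized internally).
#' @param pixel_size_um Physical pixel size (um/px).
#' @param sampling_rate Frame rate (Hz).
#' @param search_radius Search radius in pixels (default 10).
#' @param min_correlation Frames whose best correlation falls below this in
#'   more than 5% of frames abort tracking (default 0.5).
#' @return A [deflection_trace()] (deflections in m).
#' @export
track_posts <- function(video, templates, pixel_size_um, sampling_rate,
                        search_radius = 10L, min_correlation = 0.5) {
  stopifnot(is.array(video), length(dim(video)) == 3)
  nr <- dim(video)[1]; nc <- dim(video)[2]; nt <- dim(video)[3]
  defl <- vector("list", length(templates))
  for (p in seq_along(templates)) {
    tp <- templates[[p]]
    if (tp$h > nr || tp$w > nc) stop("track_posts: template larger than frame")
    rows <- tp$y0:(tp$y0 + tp$h - 1); cols <- tp$x0:(tp$x0 + tp$w - 1)
    if (min(rows) < 1 || max(rows) > nr || min(cols) < 1 || max(cols) > nc) {
      stop("track_posts: template region outside frame")
    }
    templ <- video[rows, cols, 1]
    tv <- as.vector(templ) - mean(templ)
    tn <- sqrt(sum(tv^2))
    if (tn == 0) stop("track_posts: constant template; cannot track")
    toward <- tp$toward / sqrt(sum(tp$toward^2))
    disp <- matrix(NA_real_, nt, 2)
    n_bad <- 0L
    offs <- seq(-search_radius, search_radius)
    for (f in seq_len(nt)) {
      cc <- matrix(-Inf, length(offs), length(offs))
      for (i in seq_along(offs)) {
        r2 <- rows + offs[i]
        if (min(r2) < 1 || max(r2) > nr) next
        for (j in seq_along(offs)) {
          c2 <- cols + offs[j]
          if (min(c2) < 1 || max(c2) > nc) next
          patch <- video[r2, c2, f]
          pv <- as.vector(patch) - mean(patch)
          pn <- sqrt(sum(pv^2))
          cc[i, j] <- if (pn == 0) 0 else sum(pv * tv) / (pn * tn)
        }
      }
      best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (max(cc) < min_correlation) n_bad <- n_bad + 1L
      dy <- offs[best[1]]; dx <- offs[best[2]]
      # parabolic sub-pixel refinement along each axis
      sub <- function(cm1, c0, cp1) {
        den <- cm1 - 2 * c0 + cp1
        if (!is.finite(den) || den >= 0) return(0)
        0.5 * (cm1 - cp1) / den
      }
      if (best[1] > 1 && best[1] < length(offs) &&
          is.finite(cc[best[1] - 1, best[2]]) && is.finite(cc[best[1] + 1, best[2]])) {
        dy <- dy + sub(cc[best[1] - 1, best[2]], cc[best[1], best[2]], cc[best[1] + 1, best[2]])
      }
      if (best[2] > 1 && best[2] < length(offs) &&
          is.finite(cc[best[1], best[2] - 1]) && is.finite(cc[best[1], best[2] + 1])) {
        dx <- dx + sub(cc[best[1], best[2] - 1], cc[best[1], best[2]], cc[best[1], best[2] + 1])
      }
      disp[f, ] <- c(dx, dy)
    }
    if (n_bad > 0.05 * nt) {
      stop("track_posts: correlation below threshold in >5% of frames; tracking failed")
    }
    defl[[p]] <- (disp[, 1] * toward[1] + disp[, 2] * toward[2]) * pixel_size_um * 1e-6
  }
  time <- (seq_len(nt) - 1) / sampling_rate
  if (length(defl) == 1) {
    deflection_trace(time, defl[[1]], sampling_rate = sampling_rate)
  } else {
    deflection_trace(time, defl[[1]], defl[[2]], sampling_rate = sampling_rate)
  }
}
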