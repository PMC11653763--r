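#' Calcium fluorescence trace
#'
#' @param time Time stamps (s), uniform grid.
#' @param intensity Fluorescence intensity (arbitrary units), `>= 0`.
#' @param normalized Optional pre-computed dF/F0 values.
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(time, intensity, normalized = NULL) {
  stopifnot(is.numeric(time), is.numeric(intensity),
            length(time) == length(intensity))
  if (any(intensity < 0)) stop("calcium_trace: intensity must be >= 0")
  dt <- diff(time)
  if (any(dt <= 0)) stop("calcium_trace: time must be strictly increasing")
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    stop("calcium_trace: time grid must be uniform")
  }
  structure(
    list(time = time, intensity = intensity, normalized = normalized,
         sampling_rate = 1 / stats::median(dt)),
    class = "calcium_trace"
  )
}

#' Normalize a calcium trace to dF/F0
#'
#' \eqn{\Delta F/F_0 = (F - F_0)/F_0} with the baseline \eqn{F_0} taken as
#' a rolling 10th-percentile of the raw intensity (tracks slow drift and
#' photobleaching while ignoring transients). The median of the normalized
#' trace sits near zero for a quiescent baseline.
#'
#' @param trace A [calcium_trace()].
#' @param window_s Baseline window in seconds (default 5).
#' @return The trace with its `normalized` field populated.
#' @export
normalize_dff <- function(trace, window_s = 5) {
  stopifnot(inherits(trace, "calcium_trace"))
  f0 <- rolling_baseline(trace$intensity, round(window_s * trace$sampling_rate))
  if (any(f0 <= 0)) stop("normalize_dff: non-positive baseline fluorescence")
  trace$normalized <- (trace$intensity - f0) / f0
  trace
}

#' Calcium flux kinetics and rhythm metrics
#'
#' From a (normalized) calcium trace: beats per minute (60 over the mean
#' inter-peak interval), peak-to-peak irregularity (sample SD of inter-peak
#' intervals), 10%-to-90% upstroke rise time, 90%-to-10% downstroke decay
#' time, and full width at half maximum, all with linear interpolation of
#' threshold crossings and averaged across peaks.
#'
#' @param trace A [calcium_trace()]; normalized with [normalize_dff()] if
#'   its `normalized` field is empty.
#' @param min_prominence_fraction Peak prominence floor (default 0.2),
#'   shared with the twitch detector.
#' @param min_separation_s Minimum peak separation (s).
#' @return An object of class `flux_metrics`: `beats_per_minute`,
#'   `irregularity` (s), `rise_time` (s), `decay_time` (s), `fwhm` (s),
#'   `n_peaks`. Irregularity requires at least 3 peaks, kinetics at least
#'   1; unavailable metrics are `NA` with a warning.
#' @export
flux_metrics <- function(trace, min_prominence_fraction = 0.2,
                         min_separation_s = 0.2) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (is.null(trace$normalized)) trace <- normalize_dff(trace)
  y <- trace$normalized
  t <- trace$time
  fs <- trace$sampling_rate
  pk <- find_peaks(y, baseline = 0, min_prominence_fraction = min_prominence_fraction,
                   min_separation = max(1L, round(min_separation_s * fs)))
  out <- structure(
    list(beats_per_minute = NA_real_, irregularity = NA_real_,
         rise_time = NA_real_, decay_time = NA_real_, fwhm = NA_real_,
         n_peaks = length(pk)),
    class = "flux_metrics"
  )
  if (!length(pk)) {
    warning("flux_metrics: no peaks detected; all metrics absent")
    return(out)
  }
  if (length(pk) >= 2) {
    iv <- diff(t[pk])
    out$beats_per_minute <- 60 / mean(iv)
    if (length(pk) >= 3) out$irregularity <- stats::sd(iv) else {
      warning("flux_metrics: fewer than 3 peaks; irregularity absent")
    }
  }
  rise <- decay <- width <- rep(NA_real_, length(pk))
  for (k in seq_along(pk)) {
    amp <- y[pk[k]]
    if (amp <= 0) next
    t10u <- crossing_time(t, y, 0.1 * amp, pk[k], -1L)
    t90u <- crossing_time(t, y, 0.9 * amp, pk[k], -1L)
    t90d <- crossing_time(t, y, 0.9 * amp, pk[k], +1L)
    t10d <- crossing_time(t, y, 0.1 * amp, pk[k], +1L)
    th_up <- crossing_time(t, y, 0.5 * amp, pk[k], -1L)
    th_dn <- crossing_time(t, y, 0.5 * amp, pk[k], +1L)
    rise[k] <- t90u - t10u
    decay[k] <- t10d - t90d
    width[k] <- th_dn - th_up
  }
  out$rise_time <- mean(rise, na.rm = TRUE)
  out$decay_time <- mean(decay, na.rm = TRUE)
  out$fwhm <- mean(width, na.rm = TRUE)
  out
}

#' @export
print.flux_metrics <- function(x, ...) {
  cat("Calcium flux metrics (", x$n_peaks, " peaks)\n", sep = "")
  cat(sprintf("  beats per minute  %.3g\n", x$beats_per_minute))
  cat(sprintf("  irregularity      %.3g s\n", x$irregularity))
  cat(sprintf("  rise / decay      %.3g / %.3g s\n", x$rise_time, x$decay_time))
  cat(sprintf("  FWHM              %.3g s\n", x$fwhm))
  invisible(x)
}

# Split a mask into n_regions equal-area tiles along the mask's principal
# axes: quantile cuts of the rotated coordinates, nx x ny grid.
tile_mask <- function(mask, n_regions = 16) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < n_regions) stop("tile_mask: mask smaller than n_regions pixels")
  nx <- floor(sqrt(n_regions))
  while (n_regions %% nx != 0) nx <- nx - 1
  ny <- n_regions / nx
  xy <- cbind(idx[, 2], idx[, 1])
  xy <- sweep(xy, 2, colMeans(xy))
  ev <- eigen(stats::cov(xy), symmetric = TRUE)$vectors
  rot <- xy %*% ev
  # cut the long axis into ny slabs, each slab into nx tiles, by quantiles
  lab <- integer(nrow(xy))
  q1 <- stats::quantile(rot[, 1], probs = seq(0, 1, length.out = ny + 1))
  g1 <- cut(rot[, 1], breaks = q1, include.lowest = TRUE, labels = FALSE)
  for (s in seq_len(ny)) {
    in_s <- which(g1 == s)
    q2 <- stats::quantile(rot[in_s, 2], probs = seq(0, 1, length.out = nx + 1))
    g2 <- cut(rot[in_s, 2], breaks = q2, include.lowest = TRUE, labels = FALSE)
    lab[in_s] <- (s - 1) * nx + g2
  }
  out <- array(0L, dim = dim(mask))
  out[idx] <- lab
  out
}

#' Regional calcium transient correlation
#'
#' Tiles the tissue mask into `n_regions` equal-area regions along the
#' tissue's principal axes, extracts the mean-intensity time course of each
#' region, and returns the average Pearson correlation coefficient over all
#' unordered region pairs. Synchronous tissues score near 1; spatially
#' uncoordinated activity scores near 0.
#'
#' @param video 3D numeric array `[row, col, frame]` of calcium
#'   fluorescence.
#' @param tissue_mask Logical matrix matching the frame size.
#' @param n_regions Number of equal-area regions (default 16).
#' @return An object of class `regional_correlation`: `n_regions`,
#'   `mean_pearson`, `traces` (frames x regions matrix).
#' @export
regional_correlation <- function(video, tissue_mask, n_regions = 16) {
  stopifnot(is.array(video), length(dim(video)) == 3, is.logical(tissue_mask))
  if (dim(video)[3] < 50) stop("regional_correlation: need at least 50 frames")
  lab <- tile_mask(tissue_mask, n_regions)
  nt <- dim(video)[3]
  traces <- matrix(NA_real_, nt, n_regions)
  flat <- matrix(video, ncol = nt)
  labv <- as.vector(lab)
  for (r in seq_len(n_regions)) {
    sel <- labv == r
    traces[, r] <- colMeans(flat[sel, , drop = FALSE])
  }
  sds <- apply(traces, 2, stats::sd)
  ok <- which(sds > 0)
  if (length(ok) < length(sds)) {
    warning("regional_correlation: ", length(sds) - length(ok),
            " constant region trace(s) excluded")
  }
  if (length(ok) < 2) stop("regional_correlation: fewer than 2 usable regions")
  cm <- stats::cor(traces[, ok, drop = FALSE])
  mean_r <- mean(cm[upper.tri(cm)])
  structure(
    list(n_regions = n_regions, mean_pearson = mean_r, traces = traces),
    class = "regional_correlation"
  )
}
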