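#' Micrometers to meters
#' @param x Value(s) in micrometers.
#' @return Value(s) in meters.
#' @export
um_to_m <- function(x) x * 1e-6

#' Meters to micrometers
#' @param x Value(s) in meters.
#' @return Value(s) in micrometers.
#' @export
m_to_um <- function(x) x * 1e6

# Rolling lower-quantile baseline. Window is in samples; quantile defaults to
# the 10th percentile, which tracks the diastolic/resting level of a trace
# with transient upward excursions while ignoring the excursions themselves.
rolling_baseline <- function(x, window, prob = 0.1) {
  n <- length(x)
  window <- max(3L, min(as.integer(window), n))
  half <- window %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- stats::quantile(x[lo:hi], probs = prob, names = FALSE, type = 7)
  }
  out
}

# Local-maximum peak detection with a topographic-prominence floor.
# Candidates are strict local maxima (ties broken to the first sample of a
# flat top). Each candidate's prominence is its height above the higher of
# the two valley minima separating it from higher ground (or the trace
# boundary); candidates below min_prominence_fraction * the largest
# prominence, or not above `baseline`, are dropped. Returns peak indices.
find_peaks <- function(x, baseline = 0, min_prominence_fraction = 0.2,
                       min_separation = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  h <- x - baseline
  dx <- diff(x)
  s_nz <- sign(dx)
  for (i in seq(2, length.out = max(0, n - 2))) if (s_nz[i] == 0) s_nz[i] <- s_nz[i - 1]
  cand <- which(s_nz[-length(s_nz)] > 0 & s_nz[-1] < 0) + 1L
  cand <- cand[h[cand] > 0]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    v <- x[p]
    i <- p; lmin <- v
    while (i > 1 && x[i - 1] <= v) { i <- i - 1; if (x[i] < lmin) lmin <- x[i] }
    i <- p; rmin <- v
    while (i < n && x[i + 1] <= v) { i <- i + 1; if (x[i] < rmin) rmin <- x[i] }
    v - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence_fraction * max(prom)
  cand <- cand[keep]
  if (!length(cand)) return(integer(0))
  # enforce minimum separation, keeping the taller peak
  if (min_separation > 1L && length(cand) > 1L) {
    keep <- cand[1]
    for (p in cand[-1]) {
      if (p - keep[length(keep)] < min_separation) {
        if (h[p] > h[keep[length(keep)]]) keep[length(keep)] <- p
      } else keep <- c(keep, p)
    }
    cand <- keep
  }
  cand
}

# Linear-interpolated crossing time of level `lev` between samples i and i+1
# of trace (t, y), searching from index `from` in direction `dir` (+1/-1).
# Returns NA if the level is never crossed.
crossing_time <- function(t, y, lev, from, dir) {
  n <- length(y)
  i <- from
  while (i + dir >= 1 && i + dir <= n) {
    j <- i + dir
    if ((y[i] - lev) * (y[j] - lev) <= 0 && y[i] != y[j]) {
      frac <- (lev - y[i]) / (y[j] - y[i])
      return(t[i] + frac * (t[j] - t[i]))
    }
    i <- j
  }
  NA_real_
}

#' Axial circular standard deviation
#'
#' Circular standard deviation of axis-valued orientations (theta and
#' theta + 180 degrees identified). Angles are doubled, the mean resultant
#' length R of the doubled angles computed (optionally weighted), and the
#' SD taken as \eqn{\frac{1}{2}\sqrt{-2 \ln R}}, mapped back to degrees.
#' Invariant under global rotation and under relabeling theta -> theta + 180.
#'
#' @param theta_deg Orientations in degrees (axial; any representative).
#' @param weights Optional non-negative weights.
#' @return SD in degrees; 0 for perfectly aligned input.
#' @export
axial_circular_sd <- function(theta_deg, weights = NULL) {
  theta_deg <- theta_deg[is.finite(theta_deg)]
  if (!length(theta_deg)) return(NA_real_)
  phi <- 2 * theta_deg * pi / 180
  if (is.null(weights)) weights <- rep(1, length(phi))
  w <- weights / sum(weights)
  R <- sqrt(sum(w * cos(phi))^2 + sum(w * sin(phi))^2)
  R <- min(R, 1)
  if (R <= 0) return(Inf)
  0.5 * sqrt(-2 * log(R)) * 180 / pi
}

#' Axial circular mean
#'
#' Mean orientation of axis-valued angles via angle doubling, in degrees in
#' [-90, 90).
#'
#' @param theta_deg Orientations in degrees.
#' @param weights Optional non-negative weights.
#' @return Mean orientation in degrees.
#' @export
axial_circular_mean <- function(theta_deg, weights = NULL) {
  theta_deg <- theta_deg[is.finite(theta_deg)]
  if (!length(theta_deg)) return(NA_real_)
  phi <- 2 * theta_deg * pi / 180
  if (is.null(weights)) weights <- rep(1, length(phi))
  m <- atan2(sum(weights * sin(phi)), sum(weights * cos(phi))) / 2 * 180 / pi
  wrap_axial(m)
}

# Wrap angle(s) in degrees to the axial range [-90, 90).
wrap_axial <- function(theta_deg) {
  out <- (theta_deg + 90) %% 180 - 90
  out[out == 90] <- -90
  out
}

# Smallest axial angular difference |a - b| in degrees, in [0, 90].
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
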