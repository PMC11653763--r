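# Shared low-level image helpers ------------------------------------------

# Normalize to [0,1] and Otsu-threshold; returns a logical mask.
# Thresholding an intensity-rescaled copy of an image gives the same mask,
# which makes downstream area fractions invariant to acquisition gain.
adaptive_mask <- function(img, background_sigma_um = NULL, pixel_size_um = 1) {
  if (!all(is.finite(img))) stop("adaptive_mask: non-finite pixels")
  if (!is.null(background_sigma_um)) {
    # brush must fit inside the image
    sig <- min(background_sigma_um / pixel_size_um,
               (min(dim(img)) - 3) / 7)
    if (sig >= 1) {
      bg <- EBImage::gblur(EBImage::Image(img), sigma = sig)
      img <- pmax(img - as.matrix(bg@.Data), 0)
    }
  }
  rng <- range(img)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  norm <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  norm > th
}

# Second-moment (principal-axis) orientation of a set of pixel coordinates.
# x = column index, y = -row index so angles are measured from the image
# x-axis, counter-clockwise positive in the conventional display. Returns
# orientation in degrees in [-90, 90), the major/minor eigenvalues, and an
# indeterminacy flag for near-isotropic objects.
pixel_orientation <- function(rows, cols) {
  x <- cols - mean(cols)
  y <- -(rows - mean(rows))
  mxx <- mean(x^2); myy <- mean(y^2); mxy <- mean(x * y)
  theta <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  ev <- 0.5 * c((mxx + myy) + sqrt((mxx - myy)^2 + 4 * mxy^2),
                (mxx + myy) - sqrt((mxx - myy)^2 + 4 * mxy^2))
  list(orientation = wrap_axial(theta), major = ev[1], minor = ev[2],
       indeterminate = ev[1] <= 0 || (ev[2] / ev[1]) > 0.9)
}

# Z-disc segmentation ------------------------------------------------------

#' Segment z-discs from a titin (or alpha-actinin) image
#'
#' Background-subtracted Otsu thresholding followed by connected-component
#' labeling; components below the minimum area are dropped. Each z-disc
#' carries its centroid (um), area (um^2) and axial orientation from the
#' second-moment principal axis of its pixels (degrees from the image
#' x-axis, counter-clockwise positive, in [-90, 90)).
#'
#' @param titin 2D numeric intensity matrix.
#' @param pixel_size_um Pixel size (um/px, isotropic in-plane).
#' @param min_area_um2 Minimum object area (default 0.3 um^2).
#' @param background_sigma_um Gaussian background-estimation scale (um);
#'   `NULL` disables background subtraction.
#' @return A data.frame with columns `id`, `x_um`, `y_um`, `area_um2`,
#'   `orientation_deg`, `indeterminate`. Zero rows (with a warning) if
#'   nothing is segmented.
#' @export
segment_zdiscs <- function(titin, pixel_size_um, min_area_um2 = 0.3,
                           background_sigma_um = 10) {
  stopifnot(is.matrix(titin), pixel_size_um > 0)
  mask <- adaptive_mask(titin, background_sigma_um, pixel_size_um)
  empty <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), orientation_deg = numeric(0),
                      indeterminate = logical(0))
  if (!any(mask)) {
    warning("segment_zdiscs: empty segmentation")
    return(empty)
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- as.matrix(lab@.Data)
  ids <- sort(unique(labm[labm > 0]))
  min_px <- min_area_um2 / pixel_size_um^2
  out <- lapply(ids, function(i) {
    px <- which(labm == i, arr.ind = TRUE)
    if (nrow(px) < min_px) return(NULL)
    o <- pixel_orientation(px[, 1], px[, 2])
    data.frame(id = i, x_um = mean(px[, 2]) * pixel_size_um,
               y_um = mean(px[, 1]) * pixel_size_um,
               area_um2 = nrow(px) * pixel_size_um^2,
               orientation_deg = o$orientation, indeterminate = o$indeterminate)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0) {
    warning("segment_zdiscs: all objects below minimum area")
    return(empty)
  }
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Myofibril grouping -------------------------------------------------------

#' Group z-discs into myofibrils by proximity and orientation
#'
#' Greedy deterministic chaining. Z-discs lie perpendicular to their
#' myofibril's axis, so from each chain end the next disc is sought along
#' the direction perpendicular to the end disc's orientation: within
#' `max_gap_um` of the end centroid, with axial orientation within
#' `max_angle_deg` of the end disc, and with the centroid displacement
#' within `max_angle_deg` of the chain axis. Ties break to the nearest
#' disc, then the lowest id; discs are processed in id order so the
#' partition is independent of input row order. Chains with fewer than
#' `min_discs` z-discs are discarded.
#'
#' @param zdiscs Data.frame from [segment_zdiscs()].
#' @param max_gap_um Maximum centroid gap between consecutive discs
#'   (default 3 um, about 1.5 sarcomere lengths).
#' @param max_angle_deg Maximum axial orientation difference and off-axis
#'   displacement angle (default 20 degrees).
#' @param min_discs Minimum z-discs per myofibril (default 3).
#' @return A data.frame with one row per myofibril: `id`, `n_discs`,
#'   `n_sarcomeres`, `length_um`, `mean_orientation_deg` (axial orientation
#'   of the chain axis), and `zdisc_ids` (list column).
#' @export
group_myofibrils <- function(zdiscs, max_gap_um = 3, max_angle_deg = 20,
                             min_discs = 3) {
  empty <- data.frame(id = integer(0), n_discs = integer(0),
                      n_sarcomeres = integer(0), length_um = numeric(0),
                      mean_orientation_deg = numeric(0))
  empty$zdisc_ids <- list()
  if (is.null(zdiscs) || nrow(zdiscs) == 0) return(empty)
  zd <- zdiscs[order(zdiscs$id), , drop = FALSE]
  n <- nrow(zd)
  xs <- zd$x_um; ys <- -zd$y_um  # y up, consistent with orientation sign
  th <- zd$orientation_deg
  assigned <- rep(FALSE, n)

  next_disc <- function(i, dir_vec) {
    # candidate discs reachable from disc i along dir_vec
    cand <- which(!assigned)
    cand <- cand[cand != i]
    if (!length(cand)) return(NA_integer_)
    dx <- xs[cand] - xs[i]; dy <- ys[cand] - ys[i]
    dist <- sqrt(dx^2 + dy^2)
    ok <- dist <= max_gap_um & dist > 0
    ok <- ok & axial_diff(th[cand], th[i]) <= max_angle_deg
    step_ang <- atan2(dy, dx) * 180 / pi
    axis_ang <- atan2(dir_vec[2], dir_vec[1]) * 180 / pi
    ok <- ok & axial_diff(step_ang, axis_ang) <= max_angle_deg
    ok <- ok & (dx * dir_vec[1] + dy * dir_vec[2]) > 0  # keep moving outward
    cand <- cand[ok]; dist <- dist[ok]
    if (!length(cand)) return(NA_integer_)
    cand[order(dist, cand)][1]
  }

  chains <- list()
  for (seed in seq_len(n)) {
    if (assigned[seed]) next
    assigned[seed] <- TRUE
    chain <- seed
    # axis: perpendicular of the seed disc orientation
    for (sgn in c(1, -1)) {
      repeat {
        end <- if (sgn == 1) chain[length(chain)] else chain[1]
        perp <- (th[end] + 90) * pi / 180
        dir_vec <- sgn * c(cos(perp), sin(perp))
        # orient the axis consistently with the chain's growth so both
        # representatives of the axial perpendicular are tried
        nxt <- next_disc(end, dir_vec)
        if (is.na(nxt)) {
          nxt <- next_disc(end, -dir_vec)
          if (is.na(nxt)) break
        }
        assigned[nxt] <- TRUE
        chain <- if (sgn == 1) c(chain, nxt) else c(nxt, chain)
      }
    }
    if (length(chain) >= min_discs) chains[[length(chains) + 1]] <- chain
  }
  if (!length(chains)) return(empty)
  rows <- lapply(seq_along(chains), function(k) {
    ch <- chains[[k]]
    px <- cbind(xs[ch], ys[ch])
    # chain axis from the principal component of the centroids
    o <- pixel_orientation(-px[, 2], px[, 1])
    seg <- diff(px)
    data.frame(id = k, n_discs = length(ch), n_sarcomeres = length(ch) - 1L,
               length_um = sum(sqrt(rowSums(seg^2))),
               mean_orientation_deg = o$orientation)
  })
  out <- do.call(rbind, rows)
  out$zdisc_ids <- lapply(chains, function(ch) zd$id[ch])
  out
}

# Alignment statistics -----------------------------------------------------

#' Sarcomere/myofibril alignment deviation
#'
#' The spread of axial myofibril orientations in a field of view, as a
#' circular standard deviation with angle doubling (orientations are
#' axes: theta and theta + 180 are the same). Lower values mean a more
#' anisotropic, aligned tissue. A plain Gaussian reading (SD of signed
#' deviations from the circular mean) is available as `method = "gaussian"`.
#'
#' @param x Either a numeric vector of orientations (degrees) or a
#'   myofibril data.frame from [group_myofibrils()].
#' @param method `"circular"` (default; doubled-angle circular SD) or
#'   `"gaussian"`.
#' @return Alignment deviation in degrees; `NA` with a warning for fewer
#'   than 2 orientations.
#' @export
alignment_deviation <- function(x, method = c("circular", "gaussian")) {
  method <- match.arg(method)
  theta <- if (is.data.frame(x)) x$mean_orientation_deg else x
  theta <- theta[is.finite(theta)]
  if (length(theta) < 2) {
    warning("alignment_deviation: fewer than 2 orientations")
    return(NA_real_)
  }
  if (method == "circular") return(axial_circular_sd(theta))
  mu <- axial_circular_mean(theta)
  dev <- wrap_axial(theta - mu)
  stats::sd(dev)
}

#' Titin-positive areal density
#'
#' Fraction of the tissue mask covered by titin-rich (myofibril) signal:
#' adaptive (Otsu) threshold of the titin channel intersected with the
#' mask, over the mask area. Invariant to intensity rescaling.
#'
#' @param titin 2D intensity matrix.
#' @param tissue_mask Logical matrix; defaults to the whole frame.
#' @param pixel_size_um Pixel size (um/px); only used for background
#'   subtraction scaling.
#' @param background_sigma_um Background-estimation scale (um) or `NULL`.
#' @return Fraction in [0, 1].
#' @export
myofibril_density <- function(titin, tissue_mask = NULL, pixel_size_um = 1,
                              background_sigma_um = NULL) {
  stopifnot(is.matrix(titin))
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, nrow(titin), ncol(titin))
  if (!any(tissue_mask)) stop("myofibril_density: empty tissue mask")
  pos <- adaptive_mask(titin, background_sigma_um, pixel_size_um)
  sum(pos & tissue_mask) / sum(tissue_mask)
}

# Fiber field --------------------------------------------------------------

#' Matrix fiber density, orientation and dispersion field
#'
#' Structure-tensor analysis of the fiber channel on a regular node grid.
#' Per node (window of `window_um` centered on the node): `density` is the
#' fiber-positive pixel fraction (global Otsu threshold), `orientation_deg`
#' is the principal stripe direction from the window-integrated structure
#' tensor, and `dispersion_deg` is the axial circular SD of per-pixel
#' gradient-normal orientations weighted by squared gradient magnitude.
#' Nodes without signal are flagged absent.
#'
#' @param fiber 2D intensity matrix of the matrix-fiber channel.
#' @param pixel_size_um Pixel size (um/px).
#' @param node_spacing_um Grid spacing between nodes (um).
#' @param window_um Edge length of the square window per node (um).
#' @param smooth_sigma_px Gaussian pre-smoothing for gradients (px).
#' @return An object of class `fiber_field`: a data.frame with `x_um`,
#'   `y_um`, `density`, `orientation_deg`, `dispersion_deg`, `absent`.
#' @export
fiber_field <- function(fiber, pixel_size_um, node_spacing_um = 10,
                        window_um = 10, smooth_sigma_px = 1) {
  stopifnot(is.matrix(fiber), pixel_size_um > 0)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(fiber), sigma = smooth_sigma_px)@.Data)
  nr <- nrow(sm); nc <- ncol(sm)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- -(sm[3:nr, ] - sm[1:(nr - 2), ]) / 2  # y up
  mag2 <- gx^2 + gy^2
  posmask <- adaptive_mask(fiber)
  # stripe orientation per pixel = gradient direction rotated 90 degrees
  stripe_deg <- wrap_axial(atan2(gy, gx) * 180 / pi + 90)

  half <- max(1L, round(window_um / pixel_size_um / 2))
  step <- max(1L, round(node_spacing_um / pixel_size_um))
  rows <- seq(half + 1L, nr - half, by = step)
  cols <- seq(half + 1L, nc - half, by = step)
  sig_floor <- 1e-6 * max(mag2)
  out <- list()
  for (r in rows) for (cc in cols) {
    rs <- (r - half):(r + half); cs <- (cc - half):(cc + half)
    w <- mag2[rs, cs]
    dens <- mean(posmask[rs, cs])
    if (sum(w) <= sig_floor || dens == 0) {
      out[[length(out) + 1]] <- data.frame(
        x_um = cc * pixel_size_um, y_um = r * pixel_size_um,
        density = dens, orientation_deg = NA_real_,
        dispersion_deg = NA_real_, absent = TRUE)
      next
    }
    jxx <- sum(gx[rs, cs]^2); jyy <- sum(gy[rs, cs]^2)
    jxy <- sum(gx[rs, cs] * gy[rs, cs])
    # dominant gradient direction; stripes run perpendicular to it
    grad_dir <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
    orient <- wrap_axial(grad_dir + 90)
    disp <- axial_circular_sd(as.vector(stripe_deg[rs, cs]), weights = as.vector(w))
    out[[length(out) + 1]] <- data.frame(
      x_um = cc * pixel_size_um, y_um = r * pixel_size_um,
      density = dens, orientation_deg = orient,
      dispersion_deg = disp, absent = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("fiber_field", class(res))
  res
}
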