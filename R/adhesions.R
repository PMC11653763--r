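# 3D binary-image primitives ----------------------------------------------
# EBImage's labeling and watershed are 2D, so the few 3D primitives needed
# here (26-connected labeling, chamfer distance, ball dilation, seeded
# nucleus splitting) are implemented directly on plain 3D arrays.

# Shift a 3D array by (di, dj, dk), filling vacated voxels with `fill`.
shift3 <- function(a, di, dj, dk, fill) {
  d <- dim(a)
  out <- array(fill, d)
  si <- max(1, 1 + di):min(d[1], d[1] + di)
  sj <- max(1, 1 + dj):min(d[2], d[2] + dj)
  sk <- max(1, 1 + dk):min(d[3], d[3] + dk)
  out[si, sj, sk] <- a[si - di, sj - dj, sk - dk]
  out
}

neighbor_offsets_26 <- function() {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
}

#' Label 26-connected components of a 3D mask
#'
#' Iterative minimum-label propagation; labels are compacted to 1..n in
#' order of first (linear-index) occurrence, so the result is deterministic.
#'
#' @param mask Logical 3D array.
#' @return Integer 3D array of component labels (0 = background).
#' @export
label_components_3d <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  d <- dim(mask)
  lab <- array(Inf, d)
  lab[mask] <- which(mask)
  offs <- neighbor_offsets_26()
  repeat {
    new <- lab
    for (o in seq_len(nrow(offs))) {
      new <- pmin(new, shift3(lab, offs$di[o], offs$dj[o], offs$dk[o], Inf))
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- array(0L, d)
  if (any(mask)) {
    vals <- lab[mask]  # in linear-index order, so roots appear in order
    out[mask] <- match(vals, unique(vals))
  }
  out
}

# Chamfer (iterative) Euclidean-ish distance from foreground voxels to the
# nearest background voxel, in physical units given anisotropic voxel size.
chamfer_distance_3d <- function(mask, voxel_size_um) {
  d <- dim(mask)
  dist <- array(0, d)
  dist[mask] <- Inf
  offs <- neighbor_offsets_26()
  step <- sqrt((offs$di * voxel_size_um[2])^2 + (offs$dj * voxel_size_um[1])^2 +
                 (offs$dk * voxel_size_um[3])^2)
  repeat {
    new <- dist
    for (o in seq_len(nrow(offs))) {
      new <- pmin(new, shift3(dist, offs$di[o], offs$dj[o], offs$dk[o], Inf) + step[o])
    }
    new[!mask] <- 0
    if (identical(new, dist)) break
    dist <- new
  }
  dist
}

#' Dilate a 3D mask by a physical radius
#'
#' Union of the mask shifted by every voxel offset whose physical length is
#' at most `radius_um` (a ball-structuring-element dilation).
#'
#' @param mask Logical 3D array.
#' @param radius_um Dilation radius (um); 0 returns the mask unchanged.
#' @param voxel_size_um Voxel size `c(x, y, z)` in um.
#' @return Logical 3D array.
#' @export
dilate_mask_3d <- function(mask, radius_um, voxel_size_um) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (radius_um <= 0) return(mask)
  ni <- ceiling(radius_um / voxel_size_um[2])
  nj <- ceiling(radius_um / voxel_size_um[1])
  nk <- ceiling(radius_um / voxel_size_um[3])
  out <- mask
  for (di in -ni:ni) for (dj in -nj:nj) for (dk in -nk:nk) {
    if (di == 0 && dj == 0 && dk == 0) next
    len <- sqrt((di * voxel_size_um[2])^2 + (dj * voxel_size_um[1])^2 +
                  (dk * voxel_size_um[3])^2)
    if (len > radius_um + 1e-12) next
    out <- out | shift3(mask, di, dj, dk, FALSE)
  }
  out
}

# Object segmentation and morphometrics ------------------------------------

#' Segment 3D objects from an intensity stack
#'
#' Otsu threshold (on the normalized stack) followed by 26-connected
#' component labeling and a minimum-volume filter. Anisotropic voxel
#' scaling is applied before the principal-axis analysis: full axis
#' lengths are derived from the voxel-coordinate covariance assuming a
#' solid ellipsoid (semi-axis \eqn{a = \sqrt{5\lambda}}), and eccentricity
#' is \eqn{\sqrt{1 - (b/a)^2}} from the two largest axes.
#'
#' @param stack 3D numeric array `[row, col, slice]` (a single channel). A
#'   2D matrix is accepted with a warning and treated as one plane.
#' @param voxel_size_um Voxel size `c(x, y, z)` in um.
#' @param min_volume_um3 Minimum object volume (um^3).
#' @return An object of class `object_set_3d`: a list with `objects` (a
#'   data.frame: `id`, `volume_um3`, `x_um`, `y_um`, `z_um`, `axis_a_um`,
#'   `axis_b_um`, `axis_c_um`, `eccentricity`), `voxels` (list of linear
#'   voxel indices per object), `labels` (label array), `dim`,
#'   `voxel_size_um`.
#' @export
segment_objects_3d <- function(stack, voxel_size_um, min_volume_um3 = 0.05) {
  if (is.matrix(stack)) {
    warning("segment_objects_3d: single-plane input; falling back to 2D")
    stack <- array(stack, dim = c(dim(stack), 1))
  }
  stopifnot(is.array(stack), length(dim(stack)) == 3, length(voxel_size_um) == 3)
  rng <- range(stack)
  vox_vol <- prod(voxel_size_um)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    mask <- array(FALSE, dim(stack))
  } else {
    norm <- (stack - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > th
  }
  lab <- label_components_3d(mask)
  ids <- seq_len(max(lab))
  objects <- list(); voxels <- list()
  keep <- 0L
  for (i in ids) {
    vx <- which(lab == i)
    vol <- length(vx) * vox_vol
    if (vol < min_volume_um3) {
      lab[vx] <- 0L
      next
    }
    keep <- keep + 1L
    ai <- arrayInd(vx, dim(stack))
    xyz <- cbind(ai[, 2] * voxel_size_um[1], ai[, 1] * voxel_size_um[2],
                 ai[, 3] * voxel_size_um[3])
    ctr <- colMeans(xyz)
    if (nrow(xyz) >= 2) {
      ev <- sort(eigen(stats::cov(xyz), symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
      ev[ev < 0] <- 0
      ax <- 2 * sqrt(5 * ev)
      ecc <- if (ax[1] > 0) sqrt(max(0, 1 - (ax[2] / ax[1])^2)) else NA_real_
    } else {
      ax <- rep(0, 3); ecc <- NA_real_
    }
    objects[[keep]] <- data.frame(
      id = keep, volume_um3 = vol, x_um = ctr[1], y_um = ctr[2], z_um = ctr[3],
      axis_a_um = ax[1], axis_b_um = ax[2], axis_c_um = ax[3], eccentricity = ecc)
    voxels[[keep]] <- vx
  }
  obj <- if (keep) do.call(rbind, objects) else
    data.frame(id = integer(0), volume_um3 = numeric(0), x_um = numeric(0),
               y_um = numeric(0), z_um = numeric(0), axis_a_um = numeric(0),
               axis_b_um = numeric(0), axis_c_um = numeric(0),
               eccentricity = numeric(0))
  structure(list(objects = obj, voxels = voxels, labels = lab,
                 dim = dim(stack), voxel_size_um = voxel_size_um),
            class = "object_set_3d")
}

#' Voxel-overlap colocalization fraction
#'
#' Fraction of object voxels falling inside the reference mask after the
#' reference has been dilated by `dilation_um` (a small dilation absorbs
#' chromatic/registration offsets between channels). Monotonically
#' non-decreasing in the dilation radius.
#'
#' @param objects An `object_set_3d` from [segment_objects_3d()].
#' @param reference_mask Logical 3D array on the same voxel grid.
#' @param dilation_um Reference dilation radius (um, default 0.25).
#' @return Fraction in [0, 1]; `NA` with a warning when there are no
#'   object voxels.
#' @export
coloc_fraction <- function(objects, reference_mask, dilation_um = 0.25) {
  stopifnot(inherits(objects, "object_set_3d"))
  stopifnot(identical(dim(reference_mask), objects$dim))
  vx <- unlist(objects$voxels)
  if (!length(vx)) {
    warning("coloc_fraction: no object voxels")
    return(NA_real_)
  }
  ref <- dilate_mask_3d(reference_mask, dilation_um, objects$voxel_size_um)
  mean(ref[vx])
}

#' Normalize a quantity per cell
#'
#' @param value Numeric value(s) (e.g. total adhesion volume in a field of
#'   view).
#' @param nuclei_count Number of nuclei in the same field of view.
#' @return `value / nuclei_count`.
#' @export
per_cell <- function(value, nuclei_count) {
  if (length(nuclei_count) != 1 || !is.finite(nuclei_count) || nuclei_count < 1) {
    stop("per_cell: nuclei_count must be a single count >= 1")
  }
  value / nuclei_count
}

#' Count nuclei in a DAPI stack
#'
#' Otsu segmentation, 26-connected labeling, then splitting of touching
#' nuclei: local maxima of the 3D chamfer distance map seed a
#' watershed-style count, with seeds closer than `min_separation_um`
#' merged (tallest first).
#'
#' @param dapi 3D numeric array of the DAPI channel.
#' @param voxel_size_um Voxel size `c(x, y, z)` in um.
#' @param min_volume_um3 Minimum nucleus volume (um^3).
#' @param min_separation_um Minimum seed separation (um, default 2).
#' @return Integer nucleus count (0 allowed, with a warning).
#' @export
count_nuclei <- function(dapi, voxel_size_um, min_volume_um3 = 5,
                         min_separation_um = 2) {
  seg <- suppressWarnings(
    segment_objects_3d(dapi, voxel_size_um, min_volume_um3 = min_volume_um3))
  if (nrow(seg$objects) == 0) {
    warning("count_nuclei: no nuclei found")
    return(0L)
  }
  mask <- seg$labels > 0
  dist <- chamfer_distance_3d(mask, voxel_size_um)
  offs <- neighbor_offsets_26()
  is_max <- mask
  for (o in seq_len(nrow(offs))) {
    nb <- shift3(dist, offs$di[o], offs$dj[o], offs$dk[o], 0)
    is_max <- is_max & (dist >= nb)
  }
  cand <- which(is_max & dist > 0)
  if (!length(cand)) return(nrow(seg$objects))
  ai <- arrayInd(cand, dim(mask))
  xyz <- cbind(ai[, 2] * voxel_size_um[1], ai[, 1] * voxel_size_um[2],
               ai[, 3] * voxel_size_um[3])
  ord <- order(-dist[cand], cand)
  acc <- integer(0)
  for (i in ord) {
    if (!length(acc)) { acc <- i; next }
    dmin <- min(sqrt(rowSums((xyz[acc, , drop = FALSE] -
                                matrix(xyz[i, ], length(acc), 3, byrow = TRUE))^2)))
    if (dmin >= min_separation_um) acc <- c(acc, i)
  }
  length(acc)
}

#' Intercalated-disc to costamere vinculin ratio
#'
#' Classifies vinculin voxels by which (dilated) reference they overlap:
#' N-cadherin overlap marks intercalated-disc (cell-cell junction)
#' vinculin, titin overlap marks costameric vinculin. Voxels overlapping
#' both references are assigned to the intercalated disc. The ratio is
#' ICD voxels over costameric voxels.
#'
#' @param vinculin_objects An `object_set_3d` of vinculin puncta.
#' @param ncad_mask,titin_mask Logical 3D reference masks on the same grid.
#' @param dilation_um Reference dilation (um, default 0.25).
#' @return Ratio `>= 0`; `NA` with a warning when no costameric voxels
#'   exist.
#' @export
icd_costamere_ratio <- function(vinculin_objects, ncad_mask, titin_mask,
                                dilation_um = 0.25) {
  stopifnot(inherits(vinculin_objects, "object_set_3d"))
  vox <- unlist(vinculin_objects$voxels)
  if (!length(vox)) {
    warning("icd_costamere_ratio: no vinculin voxels")
    return(NA_real_)
  }
  vs <- vinculin_objects$voxel_size_um
  nc <- dilate_mask_3d(ncad_mask, dilation_um, vs)
  tt <- dilate_mask_3d(titin_mask, dilation_um, vs)
  icd <- sum(nc[vox])
  costamere <- sum(tt[vox] & !nc[vox])
  if (costamere == 0) {
    warning("icd_costamere_ratio: zero costameric voxels; ratio undefined")
    return(NA_real_)
  }
  icd / costamere
}

#' Costameric vinculin intensity map
#'
#' Vinculin intensity restricted to pixels overlapping the (z-disc) titin
#' mask — the operational definition of "costameric vinculin" used by the
#' subregion regression.
#'
#' @param vinculin 2D vinculin intensity matrix.
#' @param titin_mask Logical matrix of titin-positive pixels.
#' @return Matrix of masked vinculin intensity.
#' @export
costameric_vinculin_map <- function(vinculin, titin_mask) {
  stopifnot(is.matrix(vinculin), identical(dim(vinculin), dim(titin_mask)))
  vinculin * titin_mask
}

#' Subregion regression of maturation marker on costameric vinculin
#'
#' Tiles the tissue mask into square regions of edge `region_size_um`
#' (roughly one cardiomyocyte), takes the per-region mean intensity of the
#' two maps over mask pixels, and fits ordinary least squares of the
#' maturation-marker mean (e.g. MLC-2v) on the costameric-vinculin mean.
#'
#' @param mlc2v 2D intensity matrix (response).
#' @param costameric_vinculin 2D intensity matrix (predictor), e.g. from
#'   [costameric_vinculin_map()].
#' @param tissue_mask Logical matrix; defaults to the whole frame.
#' @param pixel_size_um Pixel size (um/px).
#' @param region_size_um Region edge length (um, default 30).
#' @return An object of class `subregion_regression`: `slope`, `intercept`,
#'   `r_squared`, `n_regions`, `regions` (per-region table), `region_size_um`.
#' @export
subregion_regression <- function(mlc2v, costameric_vinculin, tissue_mask = NULL,
                                 pixel_size_um = 1, region_size_um = 30) {
  stopifnot(is.matrix(mlc2v), identical(dim(mlc2v), dim(costameric_vinculin)))
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, nrow(mlc2v), ncol(mlc2v))
  side <- max(1L, round(region_size_um / pixel_size_um))
  nr <- nrow(mlc2v); nc <- ncol(mlc2v)
  rows <- seq(1L, nr, by = side); cols <- seq(1L, nc, by = side)
  recs <- list()
  for (r0 in rows) for (c0 in cols) {
    rs <- r0:min(nr, r0 + side - 1L); cs <- c0:min(nc, c0 + side - 1L)
    m <- tissue_mask[rs, cs]
    if (!any(m)) next
    recs[[length(recs) + 1]] <- data.frame(
      row0 = r0, col0 = c0,
      mlc2v_intensity = mean(mlc2v[rs, cs][m]),
      costameric_vinculin_intensity = mean(costameric_vinculin[rs, cs][m]))
  }
  tab <- do.call(rbind, recs)
  if (is.null(tab) || nrow(tab) < 5) {
    stop("subregion_regression: fewer than 5 regions; regression underpowered")
  }
  if (stats::sd(tab$costameric_vinculin_intensity) == 0) {
    stop("subregion_regression: predictor constant across regions; slope undefined")
  }
  fit <- stats::lm(mlc2v_intensity ~ costameric_vinculin_intensity, data = tab)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         n_regions = nrow(tab), regions = tab,
         region_size_um = region_size_um),
    class = "subregion_regression"
  )
}
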