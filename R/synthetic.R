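# Seeded ground-truth generators for every pipeline input. Each generator
# is deterministic under a fixed seed and returns both the data and a
# machine-readable truth record, so every analysis stage can be exercised
# against known answers without microscopy data.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Difference-of-exponentials transient kernel, normalized to unit peak.
# The simplest smooth shape with separate rise and decay time constants;
# used for both twitch deflections and calcium transients.
twitch_kernel <- function(t, rise_tau, decay_tau) {
  stopifnot(decay_tau > rise_tau)
  tpk <- rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
  peak <- exp(-tpk / decay_tau) - exp(-tpk / rise_tau)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / decay_tau) - exp(-t[pos] / rise_tau)) / peak
  out
}

# Closed-form (numeric root-finding on the continuous kernel) crossing
# times of the unit-peak kernel; the independent truth for kinetics tests.
kernel_crossings <- function(rise_tau, decay_tau) {
  tpk <- rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
  g <- function(t) twitch_kernel(t, rise_tau, decay_tau)
  up <- function(lev) stats::uniroot(function(t) g(t) - lev, c(0, tpk), tol = 1e-12)$root
  t_end <- tpk + decay_tau * 60
  dn <- function(lev) stats::uniroot(function(t) g(t) - lev, c(tpk, t_end), tol = 1e-12)$root
  list(
    peak_time = tpk,
    rise_10_90 = up(0.9) - up(0.1),
    decay_90_10 = dn(0.1) - dn(0.9),
    fwhm = dn(0.5) - up(0.5)
  )
}

# Jittered beat times: intervals 1/rate + N(0, jitter_sd), truncated to
# stay positive, cumulated from the first beat at 1/rate.
beat_times <- function(rate, duration, interval_jitter_sd) {
  n <- ceiling(rate * duration) + 5
  iv <- pmax(1 / rate + stats::rnorm(n, 0, interval_jitter_sd), 0.2 / rate)
  bt <- 1 / rate + c(0, cumsum(iv))
  bt[bt < duration - 0.2]
}

#' Generate a synthetic twitch deflection trace
#'
#' A sum of stereotyped difference-of-exponential twitches at jittered beat
#' times plus white Gaussian noise, on both post channels independently.
#'
#' @param amplitude Peak per-post deflection (m).
#' @param rate Beat rate (Hz).
#' @param interval_jitter_sd SD of inter-beat intervals (s).
#' @param noise_sd_fraction Additive noise SD as a fraction of amplitude.
#' @param duration Trace duration (s).
#' @param sampling_rate Sampling rate (Hz, default 65).
#' @param rise_tau,decay_tau Kernel time constants (s).
#' @param seed RNG seed.
#' @return A list with `trace` (a [deflection_trace()]) and `truth`
#'   (amplitude, beat times, intervals, taus).
#' @export
gen_twitch_trace <- function(amplitude = 5e-6, rate = 1,
                             interval_jitter_sd = 0, noise_sd_fraction = 0.05,
                             duration = 30, sampling_rate = 65,
                             rise_tau = 0.03, decay_tau = 0.08, seed = 1) {
  stopifnot(amplitude > 0, rate > 0)
  if (rate * duration < 1) stop("gen_twitch_trace: rate * duration < 1 (no beats fit)")
  with_seed(seed, {
    t <- seq(0, duration, by = 1 / sampling_rate)
    bt <- beat_times(rate, duration, interval_jitter_sd)
    clean <- numeric(length(t))
    for (b in bt) clean <- clean + twitch_kernel(t - b, rise_tau, decay_tau)
    clean <- clean * amplitude
    left <- clean + stats::rnorm(length(t), 0, noise_sd_fraction * amplitude)
    right <- clean + stats::rnorm(length(t), 0, noise_sd_fraction * amplitude)
    list(
      trace = deflection_trace(t, left, right, sampling_rate = NULL),
      truth = list(amplitude = amplitude, rate = rate, beat_times = bt,
                   intervals = diff(bt), rise_tau = rise_tau,
                   decay_tau = decay_tau, seed = seed)
    )
  })
}

#' Generate a synthetic calcium fluorescence trace
#'
#' Raw fluorescence `baseline * (1 + peak_dff * sum of kernels)` plus
#' noise; the truth record carries the analytic 10-90% rise, 90-10% decay
#' and FWHM of the continuous kernel (numeric root-finding, independent of
#' the sampled trace).
#'
#' @param baseline Baseline fluorescence (a.u.).
#' @param peak_dff True peak dF/F0 of a single transient.
#' @param rise_tau,decay_tau Kernel time constants (s).
#' @param rate Beat rate (Hz).
#' @param interval_jitter_sd SD of inter-beat intervals (s).
#' @param noise_sd Additive noise SD (a.u.).
#' @param duration Trace duration (s).
#' @param sampling_rate Sampling rate (Hz).
#' @param seed RNG seed.
#' @return A list with `trace` (a [calcium_trace()]) and `truth`.
#' @export
gen_calcium_trace <- function(baseline = 100, peak_dff = 0.5,
                              rise_tau = 0.05, decay_tau = 0.2, rate = 1,
                              interval_jitter_sd = 0, noise_sd = 0,
                              duration = 30, sampling_rate = 65, seed = 1) {
  stopifnot(baseline > 0, rise_tau > 0, decay_tau > rise_tau)
  if (rate * duration < 1) stop("gen_calcium_trace: rate * duration < 1")
  with_seed(seed, {
    t <- seq(0, duration, by = 1 / sampling_rate)
    bt <- beat_times(rate, duration, interval_jitter_sd)
    flux <- numeric(length(t))
    for (b in bt) flux <- flux + twitch_kernel(t - b, rise_tau, decay_tau)
    f <- baseline * (1 + peak_dff * flux) + stats::rnorm(length(t), 0, noise_sd)
    f <- pmax(f, 0)
    cr <- kernel_crossings(rise_tau, decay_tau)
    list(
      trace = calcium_trace(t, f),
      truth = list(baseline = baseline, peak_dff = peak_dff,
                   rise_tau = rise_tau, decay_tau = decay_tau,
                   beat_times = bt, intervals = diff(bt),
                   rise_10_90 = cr$rise_10_90, decay_90_10 = cr$decay_90_10,
                   fwhm = cr$fwhm, seed = seed)
    )
  })
}

#' Generate a synthetic sarcomere (z-disc band) image
#'
#' Myofibril tracks with axial orientations drawn from a wrapped normal
#' around `mean_orientation_deg`; along each track, z-disc bands (thin
#' rectangles perpendicular to the track) at `sarcomere_spacing_um`.
#' Tracks are placed by rejection so bands never touch, making per-band
#' ground truth exact. Placement continues until the requested coverage is
#' reached.
#'
#' @param image_size_px Square image edge (px).
#' @param pixel_size_um Pixel size (um/px).
#' @param sarcomere_spacing_um Band spacing along a track (um, default 1.9).
#' @param band_width_um Band extent along the track (um).
#' @param band_length_um Band extent across the track (um).
#' @param mean_orientation_deg Mean track orientation (degrees, axial).
#' @param orientation_dispersion_sd_deg Wrapped-normal SD of track
#'   orientations (degrees).
#' @param coverage_fraction Target titin-positive area fraction.
#' @param background_noise_sd Gaussian background noise SD (signal = 1).
#' @param n_discs_per_track Bands per track.
#' @param track_centers_um Optional matrix of track centers (x, y in um,
#'   y measured downward like row indices) to bypass random placement.
#' @param track_orientations_deg Optional fixed orientations, recycled over
#'   tracks.
#' @param allow_overlap Allow tracks to overlap previously painted bands
#'   (needed for dense coverage, where real myofibrils also merge). With
#'   overlap the per-band truth may describe merged objects; the realized
#'   coverage stays exact.
#' @param clearance_um Minimum clearance between bands of different tracks.
#' @param seed RNG seed.
#' @return A list with `image` (matrix), `truth` (band centroids in image
#'   coordinates, band and track orientations, realized coverage).
#' @export
gen_sarcomere_image <- function(image_size_px = 256, pixel_size_um = 0.2,
                                sarcomere_spacing_um = 1.9,
                                band_width_um = 0.5, band_length_um = 2,
                                mean_orientation_deg = 0,
                                orientation_dispersion_sd_deg = 10,
                                coverage_fraction = 0.06,
                                background_noise_sd = 0.02,
                                n_discs_per_track = 6,
                                track_centers_um = NULL,
                                track_orientations_deg = NULL,
                                allow_overlap = FALSE,
                                clearance_um = 0.4, seed = 1) {
  stopifnot(sarcomere_spacing_um > band_width_um,
            coverage_fraction >= 0, coverage_fraction <= 1)
  with_seed(seed, {
    n <- image_size_px
    ps <- pixel_size_um
    img <- matrix(0, n, n)
    painted <- matrix(FALSE, n, n)
    # pixel centers in physical coordinates (x right, y up)
    colx <- (seq_len(n)) * ps
    rowy <- -(seq_len(n)) * ps
    truth_bands <- list()
    track_orients <- numeric(0)

    paint_track <- function(cx, cy, theta_deg, dry_clearance) {
      # returns band pixel sets (and clearance test) or NULL on collision
      u <- c(cos(theta_deg * pi / 180), sin(theta_deg * pi / 180))
      v <- c(-u[2], u[1])
      offs <- (seq_len(n_discs_per_track) - (n_discs_per_track + 1) / 2) *
        sarcomere_spacing_um
      bands <- vector("list", n_discs_per_track)
      for (b in seq_len(n_discs_per_track)) {
        bc <- c(cx, cy) + offs[b] * u
        hw <- band_width_um / 2; hl <- band_length_um / 2
        ex <- abs(u[1]) * (hw + dry_clearance) + abs(v[1]) * (hl + dry_clearance)
        ey <- abs(u[2]) * (hw + dry_clearance) + abs(v[2]) * (hl + dry_clearance)
        cr <- which(colx >= bc[1] - ex & colx <= bc[1] + ex)
        rr <- which(rowy >= bc[2] - ey & rowy <= bc[2] + ey)
        if (!length(cr) || !length(rr)) return(NULL)
        px <- expand.grid(row = rr, col = cr)
        dx <- colx[px$col] - bc[1]; dy <- rowy[px$row] - bc[2]
        au <- dx * u[1] + dy * u[2]; av <- dx * v[1] + dy * v[2]
        core <- abs(au) <= hw & abs(av) <= hl
        guard <- abs(au) <= hw + dry_clearance & abs(av) <= hl + dry_clearance
        if (!allow_overlap &&
            any(painted[cbind(px$row[guard], px$col[guard])])) return(NULL)
        bands[[b]] <- list(center = bc, rows = px$row[core], cols = px$col[core])
      }
      bands
    }

    add_track <- function(cx, cy, theta) {
      bands <- paint_track(cx, cy, theta, clearance_um)
      if (is.null(bands)) return(FALSE)
      for (b in bands) {
        if (!length(b$rows)) next
        painted[cbind(b$rows, b$cols)] <<- TRUE
        truth_bands[[length(truth_bands) + 1]] <<- data.frame(
          x_um = b$center[1], y_um = -b$center[2],
          orientation_deg = wrap_axial(theta + 90),
          track_orientation_deg = wrap_axial(theta))
      }
      track_orients <<- c(track_orients, wrap_axial(theta))
      TRUE
    }

    if (!is.null(track_centers_um)) {
      ths <- rep_len(if (is.null(track_orientations_deg)) mean_orientation_deg
                     else track_orientations_deg, nrow(track_centers_um))
      for (i in seq_len(nrow(track_centers_um))) {
        ok <- add_track(track_centers_um[i, 1], -track_centers_um[i, 2], ths[i])
        if (!ok) stop("gen_sarcomere_image: explicit track placement collides")
      }
    } else {
      target_px <- coverage_fraction * n^2
      margin <- (n_discs_per_track / 2 * sarcomere_spacing_um + band_length_um)
      fails <- 0L
      # draw each track's orientation once and retry only its center, so
      # accepted orientations remain an unbiased sample of the wrapped
      # normal (deviant tracks collide more often and would otherwise be
      # under-represented)
      while (sum(painted) < target_px) {
        theta <- wrap_axial(stats::rnorm(1, mean_orientation_deg,
                                         orientation_dispersion_sd_deg))
        ok <- FALSE
        for (att in seq_len(500)) {
          cx <- stats::runif(1, margin, n * ps - margin)
          cy <- stats::runif(1, -(n * ps - margin), -margin)
          if (add_track(cx, cy, theta)) { ok <- TRUE; break }
        }
        if (!ok) {
          fails <- fails + 1L
          if (fails > 20L) {
            stop("gen_sarcomere_image: requested coverage infeasible at this geometry")
          }
        }
      }
    }
    img[painted] <- 1
    img <- img + matrix(stats::rnorm(n^2, 0, background_noise_sd), n, n)
    bands_df <- if (length(truth_bands)) do.call(rbind, truth_bands) else
      data.frame(x_um = numeric(0), y_um = numeric(0),
                 orientation_deg = numeric(0), track_orientation_deg = numeric(0))
    list(
      image = img,
      truth = list(bands = bands_df, track_orientations_deg = track_orients,
                   coverage = mean(painted), pixel_size_um = ps,
                   mean_orientation_deg = mean_orientation_deg,
                   orientation_dispersion_sd_deg = orientation_dispersion_sd_deg,
                   seed = seed)
    )
  })
}

#' Generate a synthetic multi-channel 3D adhesion stack
#'
#' Builds titin (z-disc band slabs), vinculin (ellipsoidal puncta),
#' N-cadherin (a cell-boundary slab) and DAPI (spherical nuclei) channels
#' on a common voxel grid. A `planted_coloc_fraction` of vinculin objects
#' is centered inside the titin band mask, a `planted_icd_fraction` inside
#' the N-cadherin slab, and the remainder is placed clear of both
#' references; objects never overlap each other, so per-object truth is
#' exact.
#'
#' @param stack_dim Voxel dimensions `c(rows, cols, slices)`.
#' @param voxel_size_um Voxel size `c(x, y, z)` (um).
#' @param n_objects Number of vinculin puncta.
#' @param volume_range Ellipsoid volume range (um^3), sampled uniformly.
#' @param axis_ratio_range Long/short axis ratio range, sampled uniformly.
#' @param planted_coloc_fraction Fraction of puncta planted on titin.
#' @param planted_icd_fraction Fraction planted on N-cadherin.
#' @param n_nuclei Number of DAPI nuclei.
#' @param nucleus_radius_um Nucleus radius (um).
#' @param nuclei_centers_um Optional explicit nucleus centers (x, y, z um).
#' @param clearance_um Minimum clearance of "free" puncta from both
#'   reference masks and between any two puncta.
#' @param seed RNG seed.
#' @return A list with `channels` (named list of 3D arrays: `titin`,
#'   `vinculin`, `ncadherin`, `dapi`), `masks` (logical titin/ncadherin
#'   masks), `voxel_size_um`, and `truth` (per-object table with planted
#'   group, true axes, eccentricity and voxel volume; nucleus centers).
#' @export
gen_adhesion_stack <- function(stack_dim = c(64, 64, 16),
                               voxel_size_um = c(0.25, 0.25, 0.5),
                               n_objects = 12, volume_range = c(0.3, 1.2),
                               axis_ratio_range = c(1.3, 2.2),
                               planted_coloc_fraction = 0.5,
                               planted_icd_fraction = 0,
                               n_nuclei = 6, nucleus_radius_um = 1.5,
                               nuclei_centers_um = NULL,
                               clearance_um = 0.75, seed = 1) {
  stopifnot(planted_coloc_fraction + planted_icd_fraction <= 1)
  with_seed(seed, {
    d <- stack_dim
    vs <- voxel_size_um
    # physical coordinates of voxel centers
    X <- array(rep(seq_len(d[2]) * vs[1], each = d[1]), d)
    Y <- array(rep(seq_len(d[1]) * vs[2], times = d[2]), d)
    Z <- array(rep(seq_len(d[3]) * vs[3], each = d[1] * d[2]), d)
    ext <- c(d[2] * vs[1], d[1] * vs[2], d[3] * vs[3])

    # reference regions sized so whole puncta fit inside them: a titin-rich
    # (z-disc) block on the left and an N-cadherin (cell boundary) slab on
    # the right, separated by a clear corridor for "free" puncta
    titin_box <- rbind(c(0.05 * ext[1], 0.40 * ext[1]),
                       c(0.05 * ext[2], 0.95 * ext[2]),
                       c(0.15 * ext[3], 0.85 * ext[3]))
    ncad_box <- rbind(c(0.75 * ext[1], 0.95 * ext[1]),
                      c(0.05 * ext[2], 0.95 * ext[2]),
                      c(0.15 * ext[3], 0.85 * ext[3]))
    in_box <- function(box) {
      X >= box[1, 1] & X <= box[1, 2] & Y >= box[2, 1] & Y <= box[2, 2] &
        Z >= box[3, 1] & Z <= box[3, 2]
    }
    titin_mask <- in_box(titin_box)
    ncad_mask <- in_box(ncad_box)

    occupied <- array(FALSE, d)
    n_col <- round(planted_coloc_fraction * n_objects)
    n_icd <- round(planted_icd_fraction * n_objects)
    groups <- c(rep("coloc", n_col), rep("icd", n_icd),
                rep("free", n_objects - n_col - n_icd))
    vinc <- array(0, d)
    # keep "free" objects clear of both references by this margin
    forbid <- dilate_mask_3d(titin_mask | ncad_mask, clearance_um, vs)
    truth_obj <- list()
    for (i in seq_along(groups)) {
      placed <- FALSE
      for (att in seq_len(1000)) {
        vol <- stats::runif(1, volume_range[1], volume_range[2])
        q <- stats::runif(1, axis_ratio_range[1], axis_ratio_range[2])
        a <- (3 * vol * q^2 / (4 * pi))^(1 / 3)  # semi-axes a, a/q, a/q
        b <- a / q
        semi <- c(a, b, b)[sample(3)]  # random axis-aligned orientation
        box <- switch(groups[i],
                      coloc = titin_box,
                      icd = ncad_box,
                      free = rbind(c(0, ext[1]), c(0, ext[2]), c(0, ext[3])))
        lo <- box[, 1] + semi + vs
        hi <- box[, 2] - semi - vs
        if (any(hi <= lo)) next
        ctr <- stats::runif(3, lo, hi)
        inside <- ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
          ((Z - ctr[3]) / semi[3])^2 <= 1
        if (!any(inside)) next
        guard <- ((X - ctr[1]) / (semi[1] + clearance_um))^2 +
          ((Y - ctr[2]) / (semi[2] + clearance_um))^2 +
          ((Z - ctr[3]) / (semi[3] + clearance_um))^2 <= 1
        if (any(occupied & guard)) next
        if (groups[i] == "free" && any(forbid & inside)) next
        occupied <- occupied | inside
        vinc[inside] <- 1
        truth_obj[[i]] <- data.frame(
          group = groups[i], x_um = ctr[1], y_um = ctr[2], z_um = ctr[3],
          semi_a_um = max(semi), semi_c_um = min(semi),
          eccentricity = sqrt(1 - (min(semi) / max(semi))^2),
          volume_um3 = sum(inside) * prod(vs))
        placed <- TRUE
        break
      }
      if (!placed) stop("gen_adhesion_stack: overcrowded spec; could not place object")
    }

    # nuclei
    dapi <- array(0, d)
    if (is.null(nuclei_centers_um) && n_nuclei > 0) {
      rn <- nucleus_radius_um
      sep <- 2 * rn + 1
      gx <- seq(rn + vs[1], ext[1] - rn, by = sep)
      gy <- seq(rn + vs[2], ext[2] - rn, by = sep)
      gz <- seq(rn + vs[3], ext[3] - rn, by = sep)
      sites <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
      if (nrow(sites) < n_nuclei) stop("gen_adhesion_stack: too many nuclei for stack")
      nuclei_centers_um <- sites[sample(nrow(sites), n_nuclei), , drop = FALSE]
    }
    if (!is.null(nuclei_centers_um) && nrow(nuclei_centers_um) > 0) {
      for (i in seq_len(nrow(nuclei_centers_um))) {
        ctr <- as.numeric(nuclei_centers_um[i, ])
        inside <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <=
          nucleus_radius_um^2
        dapi[inside] <- 1
      }
    }

    list(
      channels = list(titin = titin_mask * 1, vinculin = vinc,
                      ncadherin = ncad_mask * 1, dapi = dapi),
      masks = list(titin = titin_mask, ncadherin = ncad_mask),
      voxel_size_um = vs,
      truth = list(
        objects = if (length(truth_obj)) do.call(rbind, truth_obj) else NULL,
        planted_coloc_fraction = planted_coloc_fraction,
        planted_icd_fraction = planted_icd_fraction,
        n_nuclei = if (is.null(nuclei_centers_um)) 0L else nrow(nuclei_centers_um),
        nuclei_centers_um = nuclei_centers_um,
        nucleus_radius_um = nucleus_radius_um, seed = seed)
    )
  })
}

#' Forward-generate a matrix-indentation mechanics case
#'
#' Inverts the indentation stress/strain relations: given a target modulus
#' and geometry, computes the strain, stress, tension and the post force
#' that an indentation measurement would have produced. Running the
#' returned force back through [matrix_modulus()] recovers the target to
#' machine precision, making this the oracle for the calibration chain.
#'
#' @param E_target Target elastic modulus (Pa).
#' @param geom An [indentation_geometry()].
#' @param xsec A [matrix_cross_section()].
#' @return A list: `post_force` (N), `tension`, `stress`, `strain`,
#'   `stretched_half_length`, `E_target`.
#' @export
gen_mechanics_case <- function(E_target, geom, xsec) {
  stopifnot(E_target > 0, inherits(geom, "indentation_geometry"),
            inherits(xsec, "matrix_cross_section"))
  lf <- stretched_half_length(geom)
  eps <- (2 * lf - geom$initial_span) / geom$initial_span
  if (eps <= 0) stop("gen_mechanics_case: zero-strain geometry")
  sigma <- E_target * eps
  tension <- sigma * xsec$area
  half <- geom$initial_span / 2 - geom$post_deflection
  post_force <- tension * half / lf
  list(post_force = post_force, tension = tension, stress = sigma,
       strain = eps, stretched_half_length = lf, E_target = E_target)
}

#' Generate a synthetic post-tracking video
#'
#' One or two Gaussian post tips translated horizontally by a sinusoid of
#' known amplitude (toward the tissue center), rendered analytically per
#' frame, plus optional noise.
#'
#' @param frame_dim Frame size `c(rows, cols)`.
#' @param n_frames Number of frames.
#' @param sampling_rate Frame rate (Hz).
#' @param amplitude_px Peak displacement (px).
#' @param rate Beat rate (Hz); displacement is
#'   `amplitude_px * sin(pi * rate * t)^2` (always toward center).
#' @param centers Matrix of post centers (x, y in px), one row per post.
#' @param toward List of unit vectors toward the tissue center per post.
#' @param sigma_px Gaussian spot SD (px).
#' @param noise_sd Additive noise SD.
#' @param seed RNG seed.
#' @return A list with `video` (array `[row, col, frame]`), `truth`
#'   (per-frame displacement in px, amplitude).
#' @export
gen_post_video <- function(frame_dim = c(48, 96), n_frames = 130,
                           sampling_rate = 65, amplitude_px = 8, rate = 1,
                           centers = rbind(c(20, 24), c(77, 24)),
                           toward = list(c(1, 0), c(-1, 0)),
                           sigma_px = 3, noise_sd = 0, seed = 1) {
  with_seed(seed, {
    t <- (seq_len(n_frames) - 1) / sampling_rate
    disp <- amplitude_px * sin(pi * rate * t)^2
    vid <- array(0, c(frame_dim, n_frames))
    xs <- seq_len(frame_dim[2]); ys <- seq_len(frame_dim[1])
    for (f in seq_len(n_frames)) {
      frame <- matrix(0, frame_dim[1], frame_dim[2])
      for (p in seq_len(nrow(centers))) {
        cx <- centers[p, 1] + disp[f] * toward[[p]][1]
        cy <- centers[p, 2] + disp[f] * toward[[p]][2]
        frame <- frame + outer(exp(-(ys - cy)^2 / (2 * sigma_px^2)),
                               exp(-(xs - cx)^2 / (2 * sigma_px^2)))
      }
      if (noise_sd > 0) frame <- frame + matrix(stats::rnorm(length(frame), 0, noise_sd),
                                                frame_dim[1], frame_dim[2])
      vid[, , f] <- frame
    }
    list(video = vid, truth = list(displacement_px = disp,
                                   amplitude_px = amplitude_px, rate = rate,
                                   centers = centers, seed = seed))
  })
}

#' Generate a synthetic calcium video
#'
#' A rectangular tissue whose pixels share a transient waveform, with
#' optional per-region independent noise replacing the waveform (for
#' null-correlation checks) and optional per-pixel noise.
#'
#' @param frame_dim Frame size `c(rows, cols)`.
#' @param n_frames Number of frames.
#' @param sampling_rate Frame rate (Hz).
#' @param waveform Numeric vector of length `n_frames` shared by all
#'   tissue pixels, or `NULL` for independent white-noise pixels regions.
#' @param mode `"uniform"` (all pixels share `waveform`) or
#'   `"independent"` (each of 16 tile regions gets its own white-noise
#'   trace).
#' @param mask Logical tissue mask; defaults to the full frame.
#' @param noise_sd Per-pixel additive noise SD.
#' @param seed RNG seed.
#' @return A list with `video`, `mask`, `truth`.
#' @export
gen_calcium_video <- function(frame_dim = c(32, 64), n_frames = 200,
                              sampling_rate = 65, waveform = NULL,
                              mode = c("uniform", "independent"),
                              mask = NULL, noise_sd = 0, seed = 1) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (is.null(mask)) mask <- matrix(TRUE, frame_dim[1], frame_dim[2])
    if (is.null(waveform)) {
      t <- (seq_len(n_frames) - 1) / sampling_rate
      waveform <- 1 + 0.5 * sin(2 * pi * t)
    }
    vid <- array(0, c(frame_dim, n_frames))
    if (mode == "uniform") {
      for (f in seq_len(n_frames)) {
        fr <- matrix(0, frame_dim[1], frame_dim[2])
        fr[mask] <- waveform[f]
        vid[, , f] <- fr
      }
    } else {
      lab <- tile_mask(mask, 16)
      regs <- sort(unique(lab[lab > 0]))
      for (r in regs) {
        tr <- stats::rnorm(n_frames)
        sel <- lab == r
        for (f in seq_len(n_frames)) {
          fr <- vid[, , f]; fr[sel] <- tr[f]; vid[, , f] <- fr
        }
      }
    }
    if (noise_sd > 0) vid <- vid + array(stats::rnorm(length(vid), 0, noise_sd), dim(vid))
    list(video = vid, mask = mask,
         truth = list(mode = mode, n_frames = n_frames, seed = seed))
  })
}

#' Generate paired expression maps with a planted regional relation
#'
#' Two co-registered 2D intensity maps whose per-region means obey
#' `y = intercept + slope * x` plus Gaussian noise: a piecewise-constant
#' costameric-vinculin map (x) and a maturation-marker map (y), for
#' exercising the subregion regression.
#'
#' @param image_size_px Square image edge (px).
#' @param pixel_size_um Pixel size (um/px).
#' @param region_size_um Region edge (um); regions tile the image.
#' @param slope,intercept Planted linear relation.
#' @param noise_sd Additive SD on the per-region y mean.
#' @param seed RNG seed.
#' @return A list with `mlc2v`, `costameric_vinculin` (matrices) and
#'   `truth` (slope, intercept, per-region table).
#' @export
gen_expression_maps <- function(image_size_px = 200, pixel_size_um = 1,
                                region_size_um = 20, slope = 1.5,
                                intercept = 0.1, noise_sd = 0.05, seed = 1) {
  with_seed(seed, {
    n <- image_size_px
    side <- max(1L, round(region_size_um / pixel_size_um))
    x_map <- matrix(0, n, n); y_map <- matrix(0, n, n)
    recs <- list()
    for (r0 in seq(1L, n, by = side)) for (c0 in seq(1L, n, by = side)) {
      rs <- r0:min(n, r0 + side - 1L); cs <- c0:min(n, c0 + side - 1L)
      x <- stats::runif(1, 0.2, 1)
      y <- intercept + slope * x + stats::rnorm(1, 0, noise_sd)
      x_map[rs, cs] <- x
      y_map[rs, cs] <- y
      recs[[length(recs) + 1]] <- data.frame(row0 = r0, col0 = c0, x = x, y = y)
    }
    list(mlc2v = y_map, costameric_vinculin = x_map,
         truth = list(slope = slope, intercept = intercept, noise_sd = noise_sd,
                      regions = do.call(rbind, recs), seed = seed))
  })
}
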