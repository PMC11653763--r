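# Configuration, TIFF/CSV IO and the end-to-end pipeline that joins the
# per-module analyses into one tissue report.

#' Default run configuration
#'
#' All tunable thresholds of the pipeline with their documented defaults.
#' The configuration round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param ... Named overrides of the defaults.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    pixel_size_um = 0.2,
    z_step_um = 0.5,
    post_stiffness_N_per_m = 0.41,
    tissue_width_um = 50,
    tissue_thickness_um = 15,
    tissue_span_um = 400,
    min_prominence_fraction = 0.2,
    baseline_window_s = 5,
    min_zdisc_area_um2 = 0.3,
    myofibril_max_gap_um = 3,
    myofibril_max_angle_deg = 20,
    myofibril_min_discs = 3,
    min_object_volume_um3 = 0.05,
    coloc_dilation_um = 0.25,
    n_calcium_regions = 16,
    region_size_um = 30,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("run_config: unknown option(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write an image or stack to TIFF with a calibration sidecar
#'
#' Values are affinely scaled into [0, 1] for 32-bit float TIFF storage;
#' the scaling and the physical calibration go to a `<path>.json` sidecar
#' so [read_stack()] restores the original values exactly.
#'
#' @param data 2D matrix or 3D array `[row, col, plane]`.
#' @param path Output TIFF path.
#' @param pixel_size_um In-plane pixel size (um/px).
#' @param z_step_um Plane spacing for 3D stacks (um).
#' @param channel Optional channel label.
#' @return `path`, invisibly.
#' @export
write_stack <- function(data, path, pixel_size_um, z_step_um = NULL,
                        channel = NULL) {
  stopifnot(is.numeric(data))
  if (is.matrix(data)) data <- array(data, c(dim(data), 1))
  rng <- range(data)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  norm <- (data - rng[1]) / scale
  pages <- lapply(seq_len(dim(data)[3]), function(k) norm[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = pixel_size_um, z_step_um = z_step_um,
               channel = channel, offset = rng[1], scale = scale,
               dim = dim(data))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated image stack
#'
#' Reads a (multi-page) TIFF plus its calibration sidecar when present.
#' The pixel size comes from the sidecar; a `pixel_size_um` in `config`
#' overrides it (config wins, with a message). Without either, reading
#' fails.
#'
#' @param path TIFF path.
#' @param config Optional [run_config()] or list with `pixel_size_um`
#'   (and `z_step_um`).
#' @return An object of class `image_stack`: `data` (3D array
#'   `[row, col, plane]`, 2D kept as one plane), `pixel_size_um`,
#'   `z_step_um`, `channel`.
#' @export
read_stack <- function(path, config = NULL) {
  if (!file.exists(path)) stop("read_stack: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]  # grayscale written, first plane
    arr[, , k] <- pg
  }
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  if (!is.null(meta$scale)) arr <- arr * meta$scale + meta$offset
  ps <- meta$pixel_size_um
  if (!is.null(config$pixel_size_um)) {
    if (!is.null(ps) && ps != config$pixel_size_um) {
      message("read_stack: config pixel_size_um overrides sidecar calibration")
    }
    ps <- config$pixel_size_um
  }
  if (is.null(ps)) stop("read_stack: pixel_size_um missing (no sidecar and no config override)")
  zs <- if (!is.null(config$z_step_um)) config$z_step_um else meta$z_step_um
  structure(list(data = arr, pixel_size_um = ps, z_step_um = zs,
                 channel = meta$channel),
            class = "image_stack")
}

#' Write a synthetic tissue bundle to disk
#'
#' Runs every generator under sub-seeds derived from `seed` and writes the
#' full set of pipeline inputs to `dir`: deflection and calcium trace CSVs,
#' titin image, adhesion-stack channel TIFFs, calcium video, forward
#' mechanics calibration tables, expression maps, the configuration, and a
#' `truth.json` with all ground-truth records.
#'
#' @param dir Output directory (created if needed).
#' @param config A [run_config()].
#' @param seed Master seed; generator sub-seeds are derived from it.
#' @return The directory path, invisibly.
#' @export
simulate_tissue_bundle <- function(dir, config = run_config(), seed = config$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sub <- function(k) (seed * 131L + k) %% 100000L
  truth <- list(seed = seed)

  # 60 s recording: enough beats for the split-half beat-averaged
  # amplitude estimator to stay within its 2% tolerance
  tw <- gen_twitch_trace(amplitude = 5e-6, rate = 1, interval_jitter_sd = 0.05,
                         noise_sd_fraction = 0.05, duration = 60,
                         seed = sub(1))
  utils::write.csv(
    data.frame(time_s = tw$trace$time, left_m = tw$trace$left_deflection,
               right_m = tw$trace$right_deflection),
    file.path(dir, "trace.csv"), row.names = FALSE)
  truth$twitch <- tw$truth[c("amplitude", "rate", "rise_tau", "decay_tau")]

  # 0.5 Hz leaves a quiescent gap between transients, so baseline and the
  # single-transient kinetics stay identifiable from the summed trace
  ca <- gen_calcium_trace(baseline = 100, peak_dff = 0.5, rise_tau = 0.05,
                          decay_tau = 0.2, rate = 0.5, interval_jitter_sd = 0.05,
                          noise_sd = 0.5, duration = 40, seed = sub(2))
  utils::write.csv(
    data.frame(time_s = ca$trace$time, intensity = ca$trace$intensity),
    file.path(dir, "calcium.csv"), row.names = FALSE)
  truth$calcium <- ca$truth[c("baseline", "peak_dff", "rise_10_90",
                              "decay_90_10", "fwhm")]

  sa <- gen_sarcomere_image(image_size_px = 256, pixel_size_um = 0.2,
                            mean_orientation_deg = 0,
                            orientation_dispersion_sd_deg = 15, seed = sub(3))
  write_stack(sa$image, file.path(dir, "titin.tif"), pixel_size_um = 0.2,
              channel = "titin")
  truth$sarcomere <- list(
    coverage = sa$truth$coverage,
    dispersion_sd_deg = sa$truth$orientation_dispersion_sd_deg,
    n_bands = nrow(sa$truth$bands))

  ad <- gen_adhesion_stack(planted_coloc_fraction = 0.5,
                           planted_icd_fraction = 0.25, n_objects = 12,
                           n_nuclei = 6, seed = sub(4))
  for (ch in names(ad$channels)) {
    write_stack(ad$channels[[ch]], file.path(dir, paste0("stack_", ch, ".tif")),
                pixel_size_um = ad$voxel_size_um[1],
                z_step_um = ad$voxel_size_um[3], channel = ch)
  }
  truth$adhesions <- list(
    planted_coloc_fraction = ad$truth$planted_coloc_fraction,
    planted_icd_fraction = ad$truth$planted_icd_fraction,
    n_nuclei = ad$truth$n_nuclei,
    eccentricities = ad$truth$objects$eccentricity,
    volumes_um3 = ad$truth$objects$volume_um3)

  cv <- gen_calcium_video(mode = "uniform", n_frames = 130, seed = sub(5))
  write_stack(cv$video, file.path(dir, "calcium_video.tif"), pixel_size_um = 1,
              channel = "calcium")
  write_stack(cv$mask * 1, file.path(dir, "tissue_mask.tif"), pixel_size_um = 1,
              channel = "mask")

  em <- gen_expression_maps(slope = 1.5, noise_sd = 0.05, seed = sub(6))
  write_stack(em$mlc2v, file.path(dir, "mlc2v.tif"), pixel_size_um = 1,
              channel = "mlc2v")
  write_stack(em$costameric_vinculin, file.path(dir, "costameric_vinculin.tif"),
              pixel_size_um = 1, channel = "costameric_vinculin")
  truth$regression <- list(slope = em$truth$slope, intercept = em$truth$intercept)

  # forward mechanics cases spanning the three experimental stiffness regimes
  probe <- rod_probe(400e9, 50e-6, 10e-3)
  manip <- c(10e-6, 12e-6, 15e-6)
  post <- c(4e-6, 5e-6, 7e-6)
  utils::write.csv(
    data.frame(probe_E_Pa = 400e9, probe_r_m = 50e-6, probe_L_m = 10e-3,
               manip_disp_m = manip, post_disp_m = post),
    file.path(dir, "stiffness.csv"), row.names = FALSE)
  truth$stiffness_N_per_m <- vapply(seq_along(manip), function(i) {
    bending_stiffness(probe, stiffness_measurement(manip[i], post[i]))
  }, numeric(1))

  e_targets <- c(0.68e3, 10.1e3, 17.4e3)
  geom <- indentation_geometry(400e-6, 50e-6, 2e-6)
  xsec <- matrix_cross_section(2.5e-10)
  forces <- vapply(e_targets, function(E) gen_mechanics_case(E, geom, xsec)$post_force,
                   numeric(1))
  utils::write.csv(
    data.frame(L0_m = 400e-6, dh_m = 50e-6, delta_m = 2e-6,
               post_force_N = forces, area_m2 = 2.5e-10),
    file.path(dir, "modulus.csv"), row.names = FALSE)
  truth$modulus_Pa <- e_targets

  write_run_config(config, file.path(dir, "config.yaml"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

section_or_error <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

#' Run the full analysis pipeline on a tissue bundle
#'
#' Executes every module whose inputs are present in `dir` (the layout of
#' [simulate_tissue_bundle()]) and assembles a tissue report: mechanics
#' calibration, twitch contractility, calcium kinetics and regional
#' correlation, sarcomere structure, and 3D adhesion morphometrics, plus
#' provenance (input MD5 hashes, configuration, package version). Missing
#' inputs mark their section absent; a module error is recorded in its
#' section without aborting the rest.
#'
#' @param dir Bundle directory.
#' @param config A [run_config()]; defaults to `config.yaml` in `dir` if
#'   present.
#' @return An object of class `tissue_report` (a nested list).
#' @export
run_pipeline <- function(dir, config = NULL) {
  if (is.null(config)) {
    cfg_path <- file.path(dir, "config.yaml")
    config <- if (file.exists(cfg_path)) read_run_config(cfg_path) else run_config()
  }
  report <- list(sections = list(), provenance = list())
  inputs <- list.files(dir, pattern = "\\.(csv|tif)$", full.names = TRUE)
  report$provenance <- list(
    inputs = as.list(tools::md5sum(inputs)),
    config = unclass(config),
    package_version = as.character(utils::packageVersion("cardiotug"))
  )
  any_input <- FALSE

  p <- file.path(dir, "stiffness.csv")
  if (file.exists(p)) {
    any_input <- TRUE
    report$sections$mechanics_stiffness <- section_or_error({
      tab <- read_stiffness_table(p)
      list(n = nrow(tab), stiffness_N_per_m = tab$stiffness_N_per_m)
    })
  }
  p <- file.path(dir, "modulus.csv")
  if (file.exists(p)) {
    any_input <- TRUE
    report$sections$mechanics_modulus <- section_or_error({
      tab <- read_modulus_table(p)
      list(n = nrow(tab), modulus_Pa = tab$modulus_Pa, strain = tab$strain)
    })
  }

  p <- file.path(dir, "trace.csv")
  if (file.exists(p)) {
    any_input <- TRUE
    report$sections$contractility <- section_or_error({
      tab <- utils::read.csv(p)
      tr <- deflection_trace(tab$time_s, tab$left_m,
                             if ("right_m" %in% names(tab)) tab$right_m else NULL)
      post <- post_spec(config$post_stiffness_N_per_m)
      geom <- tissue_geometry(config$tissue_span_um * 1e-6,
                              config$tissue_width_um * 1e-6,
                              config$tissue_thickness_um * 1e-6)
      tm <- twitch_metrics(tr, post, geom,
                           min_prominence_fraction = config$min_prominence_fraction)
      unclass(tm)
    })
  }

  p <- file.path(dir, "calcium.csv")
  if (file.exists(p)) {
    any_input <- TRUE
    report$sections$calcium <- section_or_error({
      tab <- utils::read.csv(p)
      fm <- flux_metrics(normalize_dff(calcium_trace(tab$time_s, tab$intensity)),
                         min_prominence_fraction = config$min_prominence_fraction)
      unclass(fm)
    })
  }

  p <- file.path(dir, "calcium_video.tif")
  pm <- file.path(dir, "tissue_mask.tif")
  if (file.exists(p) && file.exists(pm)) {
    any_input <- TRUE
    report$sections$calcium_regional <- section_or_error({
      vid <- read_stack(p)
      mask <- read_stack(pm)$data[, , 1] > 0.5
      rc <- regional_correlation(vid$data, mask, config$n_calcium_regions)
      list(n_regions = rc$n_regions, mean_pearson = rc$mean_pearson)
    })
  }

  p <- file.path(dir, "titin.tif")
  if (file.exists(p)) {
    any_input <- TRUE
    report$sections$structure <- section_or_error({
      st <- read_stack(p)
      img <- st$data[, , 1]
      zd <- segment_zdiscs(img, st$pixel_size_um,
                           min_area_um2 = config$min_zdisc_area_um2)
      mf <- group_myofibrils(zd, config$myofibril_max_gap_um,
                             config$myofibril_max_angle_deg,
                             config$myofibril_min_discs)
      list(n_zdiscs = nrow(zd), n_myofibrils = nrow(mf),
           alignment_deviation_deg = alignment_deviation(mf),
           density = myofibril_density(img),
           zdiscs = zd, myofibrils = mf[, setdiff(names(mf), "zdisc_ids")])
    })
  }

  chans <- c("vinculin", "titin", "ncadherin", "dapi")
  paths <- file.path(dir, paste0("stack_", chans, ".tif"))
  if (all(file.exists(paths))) {
    any_input <- TRUE
    report$sections$adhesions <- section_or_error({
      stacks <- lapply(paths, read_stack)
      names(stacks) <- chans
      vs <- c(stacks$vinculin$pixel_size_um, stacks$vinculin$pixel_size_um,
              if (is.null(stacks$vinculin$z_step_um)) config$z_step_um
              else stacks$vinculin$z_step_um)
      seg <- segment_objects_3d(stacks$vinculin$data, vs,
                                min_volume_um3 = config$min_object_volume_um3)
      titin_mask <- stacks$titin$data > 0.5
      ncad_mask <- stacks$ncadherin$data > 0.5
      nn <- count_nuclei(stacks$dapi$data, vs)
      cf <- coloc_fraction(seg, titin_mask, config$coloc_dilation_um)
      cfn <- coloc_fraction(seg, ncad_mask, config$coloc_dilation_um)
      icd <- icd_costamere_ratio(seg, ncad_mask, titin_mask,
                                 config$coloc_dilation_um)
      tot_vol <- sum(seg$objects$volume_um3)
      list(
        n_objects = nrow(seg$objects),
        mean_volume_um3 = mean(seg$objects$volume_um3),
        mean_eccentricity = mean(seg$objects$eccentricity, na.rm = TRUE),
        coloc_titin_fraction = cf,
        coloc_ncad_fraction = cfn,
        icd_costamere_ratio = icd,
        nuclei_count = nn,
        count_per_cell = per_cell(nrow(seg$objects), nn),
        total_volume_per_cell_um3 = per_cell(tot_vol, nn),
        objects = seg$objects)
    })
  }

  p1 <- file.path(dir, "mlc2v.tif")
  p2 <- file.path(dir, "costameric_vinculin.tif")
  if (file.exists(p1) && file.exists(p2)) {
    any_input <- TRUE
    report$sections$regression <- section_or_error({
      a <- read_stack(p1); b <- read_stack(p2)
      sr <- subregion_regression(a$data[, , 1], b$data[, , 1],
                                 pixel_size_um = a$pixel_size_um,
                                 region_size_um = 20)
      list(slope = sr$slope, intercept = sr$intercept,
           r_squared = sr$r_squared, n_regions = sr$n_regions)
    })
  }

  if (!any_input) stop("run_pipeline: no analysis inputs found in ", dir)
  errs <- vapply(report$sections, function(s) !is.null(s$error), logical(1))
  if (length(errs) && all(errs)) stop("run_pipeline: all sections failed")
  structure(report, class = "tissue_report")
}

#' Write a tissue report to JSON (plus per-object CSV tables)
#'
#' @param report A `tissue_report` from [run_pipeline()].
#' @param dir Output directory.
#' @return The report JSON path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "tissue_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slim <- report
  st <- slim$sections$structure
  if (!is.null(st$zdiscs)) {
    utils::write.csv(st$zdiscs, file.path(dir, "zdiscs.csv"), row.names = FALSE)
    utils::write.csv(st$myofibrils, file.path(dir, "myofibrils.csv"), row.names = FALSE)
    slim$sections$structure$zdiscs <- NULL
    slim$sections$structure$myofibrils <- NULL
  }
  ad <- slim$sections$adhesions
  if (!is.null(ad$objects)) {
    utils::write.csv(ad$objects, file.path(dir, "objects.csv"), row.names = FALSE)
    slim$sections$adhesions$objects <- NULL
  }
  path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(slim), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
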