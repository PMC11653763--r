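#' Rod probe specification
#'
#' Describes the calibrated rod (e.g. a tungsten microneedle on a
#' micromanipulator) used to deflect an elastomeric post during bending
#' stiffness calibration. The rod is modelled as a cantilevered Euler
#' beam of circular cross-section; its second moment of area
#' \eqn{I = \pi r^4 / 4} is derived, never stored.
#'
#' @param elastic_modulus Young's modulus of the rod material (Pa).
#' @param radius Rod radius (m).
#' @param free_length Free (cantilevered) rod length (m).
#' @return An object of class `rod_probe`.
#' @examples
#' # ~100 um diameter tungsten rod
#' rod_probe(400e9, 50e-6, 10e-3)
#' @export
rod_probe <- function(elastic_modulus, radius, free_length) {
  stopifnot(is.numeric(elastic_modulus), is.numeric(radius), is.numeric(free_length))
  if (elastic_modulus <= 0 || radius <= 0 || free_length <= 0) {
    stop("rod_probe: elastic_modulus, radius and free_length must all be strictly positive")
  }
  structure(
    list(elastic_modulus = elastic_modulus, radius = radius, free_length = free_length),
    class = "rod_probe"
  )
}

#' Second moment of area of a rod probe
#'
#' @param probe A [rod_probe()].
#' @return \eqn{\pi r^4/4} in m^4.
#' @export
rod_second_moment <- function(probe) {
  stopifnot(inherits(probe, "rod_probe"))
  pi * probe$radius^4 / 4
}

#' Force applied by a deflected rod probe
#'
#' Cantilever tip-load formula: \eqn{F = 3 d E I / L^3} with
#' \eqn{I = \pi r^4/4}. Linear in the rod deflection `d`.
#'
#' @param probe A [rod_probe()].
#' @param rod_deflection Rod tip deflection d (m), `>= 0`. Vectorised.
#' @return Force in N.
#' @export
rod_force <- function(probe, rod_deflection) {
  stopifnot(inherits(probe, "rod_probe"), is.numeric(rod_deflection))
  if (any(rod_deflection < 0)) stop("rod_force: rod_deflection must be >= 0")
  3 * rod_deflection * probe$elastic_modulus * rod_second_moment(probe) /
    probe$free_length^3
}

#' Stiffness calibration measurement
#'
#' One rod-probe push: the micromanipulator moves `manipulator_displacement`
#' while the post tip moves `post_displacement`; the difference is the rod's
#' own deflection, from which the applied force follows.
#'
#' @param manipulator_displacement Distance moved by the manipulator (m).
#' @param post_displacement Distance the post tip moved (m), symbol delta.
#' @return An object of class `stiffness_measurement`.
#' @export
stiffness_measurement <- function(manipulator_displacement, post_displacement) {
  stopifnot(is.numeric(manipulator_displacement), is.numeric(post_displacement))
  if (any(post_displacement < 0)) {
    stop("stiffness_measurement: post_displacement must be >= 0")
  }
  if (any(manipulator_displacement < post_displacement)) {
    stop("stiffness_measurement: manipulator_displacement must be >= post_displacement")
  }
  structure(
    list(
      manipulator_displacement = manipulator_displacement,
      post_displacement = post_displacement
    ),
    class = "stiffness_measurement"
  )
}

#' Post bending stiffness from a rod-probe measurement
#'
#' The rod deflection is \eqn{d = } manipulator displacement minus post
#' displacement; the post bending stiffness is the applied rod force over
#' the post displacement, \eqn{k = F_{rod}/\delta}.
#'
#' @param probe A [rod_probe()].
#' @param meas A [stiffness_measurement()].
#' @return Bending stiffness k in N/m. Vectorised over measurements.
#' @export
bending_stiffness <- function(probe, meas) {
  stopifnot(inherits(probe, "rod_probe"), inherits(meas, "stiffness_measurement"))
  delta <- meas$post_displacement
  if (any(delta == 0)) {
    stop("bending_stiffness: post_displacement is zero (degenerate measurement; k undefined)")
  }
  d <- meas$manipulator_displacement - delta
  rod_force(probe, d) / delta
}

#' Post specification
#'
#' @param bending_stiffness Post bending stiffness k (N/m).
#' @param label Optional text label (e.g. "soft", "stiff").
#' @return An object of class `post_spec`.
#' @export
post_spec <- function(bending_stiffness, label = "") {
  stopifnot(is.numeric(bending_stiffness), length(bending_stiffness) == 1)
  if (bending_stiffness <= 0) stop("post_spec: bending_stiffness must be > 0")
  structure(list(bending_stiffness = bending_stiffness, label = label),
            class = "post_spec")
}

#' Indentation geometry of a suspended fiber matrix
#'
#' Geometry of the transverse indentation test used to extract the matrix
#' elastic modulus: an indenter pressed a depth `indentation_depth` into the
#' center of a matrix of initial post-to-post span `initial_span`, pulling
#' each supporting post inward by `post_deflection`. The span is the FULL
#' matrix length; half-span quantities are derived internally.
#'
#' @param initial_span Full unstretched matrix length L0 (m).
#' @param indentation_depth Indenter depth below the matrix plane (m).
#' @param post_deflection Inward post tip deflection delta (m).
#' @return An object of class `indentation_geometry`.
#' @export
indentation_geometry <- function(initial_span, indentation_depth, post_deflection) {
  stopifnot(is.numeric(initial_span), is.numeric(indentation_depth),
            is.numeric(post_deflection))
  if (any(initial_span <= 0)) stop("indentation_geometry: initial_span must be > 0")
  if (any(indentation_depth < 0)) stop("indentation_geometry: indentation_depth must be >= 0")
  if (any(post_deflection < 0)) stop("indentation_geometry: post_deflection must be >= 0")
  if (any(post_deflection >= initial_span / 2)) {
    stop("indentation_geometry: post_deflection must be < initial_span/2")
  }
  structure(
    list(initial_span = initial_span, indentation_depth = indentation_depth,
         post_deflection = post_deflection),
    class = "indentation_geometry"
  )
}

#' Matrix cross-section
#'
#' @param area Load-bearing cross-sectional area A of the fiber matrix (m^2),
#'   typically width times thickness.
#' @return An object of class `matrix_cross_section`.
#' @export
matrix_cross_section <- function(area) {
  stopifnot(is.numeric(area))
  if (any(area <= 0)) stop("matrix_cross_section: area must be > 0")
  structure(list(area = area), class = "matrix_cross_section")
}

#' Stretched half-length of an indented fiber matrix
#'
#' The resultant length of half of the stretched matrix,
#' \eqn{L_f = \sqrt{\Delta h^2 + (L_0/2 - \delta)^2}}.
#'
#' @param geom An [indentation_geometry()].
#' @return L_f in m.
#' @export
stretched_half_length <- function(geom) {
  stopifnot(inherits(geom, "indentation_geometry"))
  half <- geom$initial_span / 2 - geom$post_deflection
  sqrt(geom$indentation_depth^2 + half^2)
}

#' Tension in an indented fiber matrix
#'
#' Force balance at the post: the post restoring force equals the
#' horizontal component of the matrix tension,
#' \eqn{F_p = T \sin\theta} with \eqn{\sin\theta = (L_0/2-\delta)/L_f},
#' so \eqn{T = F_p L_f / (L_0/2 - \delta)}.
#'
#' @param post_force Force on one post F_p (N), `>= 0`.
#' @param geom An [indentation_geometry()].
#' @return Tension T in N; always `>= post_force`.
#' @export
matrix_tension <- function(post_force, geom) {
  stopifnot(is.numeric(post_force), inherits(geom, "indentation_geometry"))
  if (any(post_force < 0)) stop("matrix_tension: post_force must be >= 0")
  half <- geom$initial_span / 2 - geom$post_deflection
  if (any(half <= 0)) stop("matrix_tension: degenerate geometry (post_deflection >= span/2)")
  post_force * stretched_half_length(geom) / half
}

#' Elastic modulus of an indented fiber matrix
#'
#' Uniaxial stress over engineering strain:
#' \eqn{\sigma = T/A}, \eqn{\epsilon = (2 L_f - L_0)/L_0}, and
#' \eqn{E = \sigma/\epsilon = T L_0 / (A (2 L_f - L_0))}.
#'
#' @param post_force Force on one post F_p (N).
#' @param geom An [indentation_geometry()].
#' @param xsec A [matrix_cross_section()].
#' @return Elastic modulus E in Pa.
#' @export
matrix_modulus <- function(post_force, geom, xsec) {
  stopifnot(inherits(xsec, "matrix_cross_section"))
  tension <- matrix_tension(post_force, geom)
  lf <- stretched_half_length(geom)
  elong <- 2 * lf - geom$initial_span
  if (any(elong <= 0)) {
    stop("matrix_modulus: zero strain (2*L_f == L0); modulus undefined")
  }
  tension * geom$initial_span / (xsec$area * elong)
}

#' Matrix strain of an indentation geometry
#'
#' Engineering strain \eqn{\epsilon = (2 L_f - L_0)/L_0}.
#'
#' @param geom An [indentation_geometry()].
#' @return Dimensionless strain.
#' @export
matrix_strain <- function(geom) {
  stopifnot(inherits(geom, "indentation_geometry"))
  (2 * stretched_half_length(geom) - geom$initial_span) / geom$initial_span
}

#' Read a bending-stiffness calibration table
#'
#' Expects CSV columns `probe_E_Pa`, `probe_r_m`, `probe_L_m`,
#' `manip_disp_m`, `post_disp_m`; returns the table with a computed
#' `stiffness_N_per_m` column.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_stiffness_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("probe_E_Pa", "probe_r_m", "probe_L_m", "manip_disp_m", "post_disp_m")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("read_stiffness_table: missing columns: ", paste(miss, collapse = ", "))
  tab$stiffness_N_per_m <- vapply(seq_len(nrow(tab)), function(i) {
    probe <- rod_probe(tab$probe_E_Pa[i], tab$probe_r_m[i], tab$probe_L_m[i])
    meas <- stiffness_measurement(tab$manip_disp_m[i], tab$post_disp_m[i])
    bending_stiffness(probe, meas)
  }, numeric(1))
  tab
}

#' Read a matrix-modulus calibration table
#'
#' Expects CSV columns `L0_m`, `dh_m`, `delta_m`, `post_force_N`, `area_m2`;
#' returns the table with computed `strain`, `stress_Pa` and `modulus_Pa`
#' columns.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_modulus_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("L0_m", "dh_m", "delta_m", "post_force_N", "area_m2")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("read_modulus_table: missing columns: ", paste(miss, collapse = ", "))
  res <- t(vapply(seq_len(nrow(tab)), function(i) {
    geom <- indentation_geometry(tab$L0_m[i], tab$dh_m[i], tab$delta_m[i])
    xsec <- matrix_cross_section(tab$area_m2[i])
    eps <- matrix_strain(geom)
    tension <- matrix_tension(tab$post_force_N[i], geom)
    c(strain = eps, stress_Pa = tension / tab$area_m2[i],
      modulus_Pa = matrix_modulus(tab$post_force_N[i], geom, xsec))
  }, numeric(3)))
  cbind(tab, as.data.frame(res))
}
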