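# Solid-body phantoms.
#
# Solids are represented implicitly by a signed distance-like field in the
# body frame (negative inside material). The renderer converts the field to a
# soft occupancy with an edge ramp about one pixel wide, which gives
# sub-pixel-smooth silhouettes without mesh bookkeeping.

#' Cube phantom with an hourglass bore
#'
#' A side-length cube with a symmetric double-frustum (hourglass) bore drilled
#' through its centre along `bore_axis`, mimicking a vertebral body with its
#' canal. The bore tapers linearly from `bore_base_diameter` at the faces to
#' `bore_waist_diameter` at the centre. The waist diameter is not a physical
#' measurement of the original phantom (unreported); it is an exposed
#' parameter.
#'
#' @param side cube edge length, mm.
#' @param bore_base_diameter bore diameter at the cube faces, mm.
#' @param bore_waist_diameter bore diameter at the cube centre, mm
#'   (`waist <= base < side`); equal diameters give a cylindrical bore.
#' @param bore_axis one of "x", "y", "z" (body frame); default "y", the coil
#'   bore direction in the study setup.
#' @return object of class `cube_solid`.
#' @export
cube_solid <- function(side = 40, bore_base_diameter = 7,
                       bore_waist_diameter = 3, bore_axis = "y") {
  if (!is.numeric(side) || side <= 0)
    stop_mrikin("side must be positive", "mrikin_param_error")
  if (bore_base_diameter < 0 || bore_waist_diameter < 0)
    stop_mrikin("bore diameters must be >= 0", "mrikin_param_error")
  if (bore_base_diameter == 0) bore_waist_diameter <- 0
  if (bore_waist_diameter > bore_base_diameter)
    stop_mrikin("bore waist diameter must not exceed the base diameter",
                "mrikin_param_error")
  if (bore_base_diameter >= side)
    stop_mrikin("bore base diameter must be smaller than the cube side",
                "mrikin_param_error")
  bore_axis <- match.arg(bore_axis, c("x", "y", "z"))
  structure(list(side = side,
                 bore_base_diameter = bore_base_diameter,
                 bore_waist_diameter = bore_waist_diameter,
                 bore_axis = bore_axis),
            class = c("cube_solid", "mrikin_solid"))
}

#' Spherical solid (calibration bead)
#' @param diameter sphere diameter, mm.
#' @param center centre in the body frame, mm.
#' @export
sphere_solid <- function(diameter = 2, center = c(0, 0, 0)) {
  if (diameter <= 0) stop_mrikin("diameter must be positive", "mrikin_param_error")
  structure(list(diameter = diameter, center = as.numeric(center)),
            class = c("sphere_solid", "mrikin_solid"))
}

#' Signed distance field of a solid
#'
#' Negative inside material. For the cube the Chebyshev box distance is used
#' (exact on faces, conservative at corners); the bore is carved out with the
#' radial distance to the local taper radius.
#' @param solid a `mrikin_solid`.
#' @param pts n x 3 matrix of body-frame points (mm).
#' @return numeric vector of length n.
#' @export
solid_sdf <- function(solid, pts) UseMethod("solid_sdf")

#' @export
solid_sdf.cube_solid <- function(solid, pts) {
  h <- solid$side / 2
  ax <- match(solid$bore_axis, c("x", "y", "z"))
  d_box <- pmax(abs(pts[, 1]) - h, abs(pts[, 2]) - h, abs(pts[, 3]) - h)
  if (solid$bore_base_diameter <= 0) return(d_box)
  perp <- setdiff(1:3, ax)
  w <- solid$bore_waist_diameter / 2
  b <- solid$bore_base_diameter / 2
  r_at <- w + (b - w) * pmin(abs(pts[, ax]), h) / h
  radial <- sqrt(pts[, perp[1]]^2 + pts[, perp[2]]^2)
  # material = inside box AND outside bore
  pmax(d_box, r_at - radial)
}

#' @export
solid_sdf.sphere_solid <- function(solid, pts) {
  d <- sweep(pts, 2, solid$center)
  sqrt(rowSums(d^2)) - solid$diameter / 2
}

#' Bounding radius of a solid about the body origin
#' @param solid a `mrikin_solid`.
#' @export
solid_radius <- function(solid) UseMethod("solid_radius")

#' @export
solid_radius.cube_solid <- function(solid) solid$side / 2 * sqrt(3)

#' @export
solid_radius.sphere_solid <- function(solid)
  sqrt(sum(solid$center^2)) + solid$diameter / 2

#' Solid volume by voxelization
#'
#' Counts voxel centres with a negative signed distance. The cube/bore field
#' classifies inside/outside exactly, so the only error is the voxel
#' discretization of the surfaces.
#' @param solid a `mrikin_solid`.
#' @param resolution voxel edge, mm.
#' @return volume in cubic mm.
#' @export
solid_volume <- function(solid, resolution = 0.25) {
  r <- solid_radius(solid)
  g <- seq(-r + resolution / 2, r, by = resolution)
  n <- length(g)
  # stream over z-slabs to bound memory
  vol <- 0
  xy <- cbind(rep(g, times = n), rep(g, each = n))
  for (z in g) {
    pts <- cbind(xy, z)
    vol <- vol + sum(solid_sdf(solid, pts) < 0)
  }
  vol * resolution^3
}

#' Analytic volume of the bored cube
#'
#' side^3 minus two frusta of half-length side/2 tapering from the base to
#' the waist radius.
#' @param solid a `cube_solid`.
#' @export
cube_volume_analytic <- function(solid) {
  h <- solid$side / 2
  R <- solid$bore_base_diameter / 2
  r <- solid$bore_waist_diameter / 2
  frustum <- pi * h / 3 * (R^2 + R * r + r^2)
  solid$side^3 - 2 * frustum
}
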