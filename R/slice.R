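# MR-like slice imaging simulator.
#
# Signal model: binary material map (saline-soaked solid bright, air/bore
# dark), thick-slab partial volume along the slice normal, in-plane Gaussian
# blur, additive Gaussian noise. No pulse-sequence contrast physics: the
# technique only uses silhouette morphology, so the two scanner sequences are
# represented purely by their pixel size and slab thickness.

#' Slice imaging specification
#'
#' @param pixel_size in-plane pixel size, mm.
#' @param thickness slab thickness, mm.
#' @param matrix image size, pixels (width `n_u`, height `n_v`).
#' @param origin world point at the image centre, mm.
#' @param normal unit slice normal (world frame).
#' @param eu,ev in-plane unit axes (world frame); derived from `normal` by a
#'   fixed convention when omitted. Pixel (u, v) (0-based, pixel-centre) maps
#'   to `origin + (u - (n_u-1)/2) * pixel_size * eu + (v - (n_v-1)/2) *
#'   pixel_size * ev`.
#' @param noise_sigma additive Gaussian noise SD as a fraction of full signal.
#' @param blur_fwhm in-plane Gaussian blur FWHM, mm.
#' @param n_depth number of partial-volume integration points across the slab.
#' @return object of class `slice_spec`.
#' @export
slice_spec <- function(pixel_size, thickness, matrix = c(256, 256),
                       origin = c(0, 0, 0), normal = c(1, 0, 0),
                       eu = NULL, ev = NULL,
                       noise_sigma = 0.03, blur_fwhm = 1, n_depth = 5) {
  if (pixel_size <= 0 || thickness <= 0)
    stop_mrikin("pixel_size and thickness must be positive", "mrikin_param_error")
  normal <- unit3(as.numeric(normal))
  if (is.null(eu) || is.null(ev)) {
    ax <- slice_axes(normal); eu <- ax$eu; ev <- ax$ev
  } else {
    eu <- unit3(as.numeric(eu)); ev <- unit3(as.numeric(ev))
  }
  structure(list(pixel_size = pixel_size, thickness = thickness,
                 matrix = as.integer(matrix), origin = as.numeric(origin),
                 normal = normal, eu = eu, ev = ev,
                 noise_sigma = noise_sigma, blur_fwhm = blur_fwhm,
                 n_depth = as.integer(n_depth)),
            class = "slice_spec")
}

#' Canonical in-plane axes for a slice normal
#'
#' Deterministic convention shared by the simulator and the registration
#' renderer; for a y-normal (axial) slice it yields eu = -x, ev = +z.
#' @param normal unit normal.
#' @export
slice_axes <- function(normal) {
  n <- unit3(normal)
  if (abs(sum(n * c(0, 1, 0))) < 0.99) {
    eu <- unit3(cross3(c(0, 1, 0), n))
  } else {
    eu <- unit3(cross3(c(0, 0, 1), n))
  }
  list(eu = eu, ev = cross3(n, eu))
}

#' Stock imaging specifications
#'
#' `t1_slice_spec`: high-resolution T1-like protocol (0.78125 mm pixels =
#' 200 mm field of view over a 256 matrix, 5 mm slab). `fast_slice_spec`:
#' fast contrast-enhanced-like protocol (0.98 mm pixels, 8 mm slab).
#' `grid_slice_spec`: T2-like calibration scan of one grid plate (0.78125 mm
#' pixels, 3 mm slab, axial through plate `plate`).
#' @param ... overrides passed to [slice_spec()].
#' @export
t1_slice_spec <- function(...) {
  do.call(slice_spec, modifyList(list(pixel_size = 200 / 256, thickness = 5), list(...)))
}

#' @rdname t1_slice_spec
#' @export
fast_slice_spec <- function(...) {
  do.call(slice_spec, modifyList(list(pixel_size = 0.98, thickness = 8), list(...)))
}

#' @rdname t1_slice_spec
#' @param plate plate index (0-based).
#' @param grid a `grid_spec`.
#' @export
grid_slice_spec <- function(plate, grid = grid_spec(), ...) {
  do.call(slice_spec, modifyList(
    list(pixel_size = 200 / 256, thickness = 3,
         origin = c(0, plate * grid$plate_spacing, 0),
         normal = c(0, 1, 0), noise_sigma = 0.02, blur_fwhm = 0.8),
    list(...)))
}

# Cached 1-D Gaussian blur operators (rows normalized to sum 1, edge-clipped).
.blur_cache <- new.env(parent = emptyenv())

blur_matrix <- function(n, sigma_px) {
  key <- sprintf("%d_%.8g", n, sigma_px)
  if (!is.null(.blur_cache[[key]])) return(.blur_cache[[key]])
  r <- max(1L, ceiling(3 * sigma_px))
  i <- seq_len(n)
  M <- outer(i, i, function(a, b) {
    d <- a - b
    ifelse(abs(d) <= r, exp(-d^2 / (2 * sigma_px^2)), 0)
  })
  M <- M / rowSums(M)
  .blur_cache[[key]] <- M
  M
}

gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  Bv <- blur_matrix(nrow(img), sigma_px)
  Bu <- blur_matrix(ncol(img), sigma_px)
  Bv %*% img %*% Bu
}

# Core renderer: soft partial-volume occupancy of a list of posed solids on
# the pixel grid of `spec`. `pixel_size` may override the nominal spec value
# (used when rendering through a calibrated volume mapping). Returns the
# pre-noise image (v rows x u columns) with an "empty" attribute.
render_scene <- function(scene, spec, pixel_size = NULL, blur = TRUE) {
  s <- if (is.null(pixel_size)) spec$pixel_size else pixel_size
  nu <- spec$matrix[1]; nv <- spec$matrix[2]
  cu <- (nu - 1) / 2; cv <- (nv - 1) / 2
  K <- spec$n_depth
  depth_off <- ((seq_len(K) - 0.5) / K - 0.5) * spec$thickness
  edge <- s  # soft-edge ramp width, one pixel
  img <- matrix(0, nv, nu)
  any_hit <- FALSE
  for (el in scene) {
    solid <- el$solid; pose <- el$pose
    center_body <- if (inherits(solid, "sphere_solid")) solid$center else c(0, 0, 0)
    cw <- pose_apply(pose, center_body)
    rel <- cw - spec$origin
    # reject solids entirely outside the slab
    if (abs(sum(rel * spec$normal)) > solid_radius(solid) + spec$thickness / 2 + edge)
      next
    uc <- sum(rel * spec$eu) / s + cu
    vc <- sum(rel * spec$ev) / s + cv
    rpx <- (solid_radius(solid) + 3 * edge) / s + 2
    u0 <- max(0, floor(uc - rpx)); u1 <- min(nu - 1, ceiling(uc + rpx))
    v0 <- max(0, floor(vc - rpx)); v1 <- min(nv - 1, ceiling(vc + rpx))
    if (u0 > u1 || v0 > v1) next
    uu <- u0:u1; vv <- v0:v1
    m <- length(uu) * length(vv)
    du <- (rep(uu, each = length(vv)) - cu) * s  # column-major over [vv, uu]
    dv <- (rep(vv, times = length(uu)) - cv) * s
    P0 <- cbind(spec$origin[1] + du * spec$eu[1] + dv * spec$ev[1],
                spec$origin[2] + du * spec$eu[2] + dv * spec$ev[2],
                spec$origin[3] + du * spec$eu[3] + dv * spec$ev[3])
    acc <- numeric(m)
    Rt <- t(pose$rotation)
    for (off in depth_off) {
      Pk <- P0
      Pk[, 1] <- Pk[, 1] + off * spec$normal[1]
      Pk[, 2] <- Pk[, 2] + off * spec$normal[2]
      Pk[, 3] <- Pk[, 3] + off * spec$normal[3]
      B <- sweep(Pk, 2, pose$translation) %*% t(Rt)
      d <- solid_sdf(solid, B)
      acc <- acc + clamp01(0.5 - d / edge)
    }
    occ <- matrix(acc / K, length(vv), length(uu))
    if (any(occ > 0)) any_hit <- TRUE
    img[vv + 1, uu + 1] <- img[vv + 1, uu + 1] + occ
  }
  img <- pmin(img, 1)
  if (blur && spec$blur_fwhm > 0)
    img <- gaussian_blur(img, spec$blur_fwhm / 2.3548 / s)
  attr(img, "empty") <- !any_hit
  img
}

#' Render an MR-like slice image of a posed scene
#'
#' Each pixel holds the partial-volume fraction of its slab column occupied by
#' solid material, blurred in-plane by `blur_fwhm` and, if `noise = TRUE`,
#' with additive Gaussian noise of SD `noise_sigma`. Deterministic given
#' `seed`.
#'
#' @param scene list of elements `list(solid = , pose = )`.
#' @param spec a `slice_spec`.
#' @param seed integer seed for the noise draw (`NULL`: current RNG stream).
#' @param noise add noise? Set `FALSE` for the noiseless image.
#' @return numeric matrix (`matrix[2]` rows x `matrix[1]` columns), attribute
#'   `"empty"` set (with a warning) when the slab misses every solid.
#' @export
render_slice <- function(scene, spec, seed = NULL, noise = TRUE) {
  img <- render_scene(scene, spec)
  if (isTRUE(attr(img, "empty")))
    warning("slice slab does not intersect any solid; background-only image")
  if (noise && spec$noise_sigma > 0) {
    nz <- with_seed(seed, matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                                 nrow(img), ncol(img)))
    e <- attr(img, "empty")
    img <- img + nz
    attr(img, "empty") <- e
  }
  img
}
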