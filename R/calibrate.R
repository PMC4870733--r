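# Slice-volume calibration: bead digitization, planar DLT and the assembled
# image<->world mapping (the "camera file" of the animation workflow).
#
# Each grid plate's control points are coplanar, which makes the classical
# 11-parameter 3-D DLT degenerate; the well-posed equivalent used here is an
# 8-parameter plane-to-image homography per plate (Hartley-normalized least
# squares) plus the known 30 mm inter-plate spacing for the out-of-plane
# scale. MR slices are tomographic, so the assembled volume model is
# affine-orthographic rather than perspective.

#' Detect bead centroids in a grid slice image
#'
#' The image is lightly smoothed (1 px Gaussian) to suppress pixel noise,
#' thresholded (Otsu, floored at a quarter of the smoothed peak), labelled
#' into connected components, size-filtered (component area within 25--400%
#' of the nominal bead disc at the stated pixel size), and each surviving
#' component's centroid is computed as the intensity-weighted mean over its
#' padded bounding box -- the symmetric soft tails give sub-pixel accuracy.
#'
#' @param image grayscale matrix (v rows x u columns) as from [render_slice()].
#' @param expected_count number of beads expected in view (16 grid beads plus
#'   any axis beads on that plate).
#' @param pixel_size image pixel size, mm.
#' @param bead_diameter nominal bead diameter, mm.
#' @return data.frame with 0-based pixel coordinates `u`, `v` and `area`
#'   (pixels); error of class `mrikin_detection_error` (candidates attached)
#'   when the count disagrees.
#' @export
detect_bead_centroids <- function(image, expected_count, pixel_size = 200 / 256,
                                  bead_diameter = 2) {
  img <- pmax(pmin(image, 1), 0)
  sm <- gaussian_blur(img, 1)
  thr <- max(EBImage::otsu(EBImage::Image(t(sm))), 0.25 * max(sm))
  bw <- sm > thr
  lab <- EBImage::bwlabel(EBImage::Image(t(bw)))
  lab <- t(EBImage::imageData(lab))      # back to v-rows x u-cols
  ncomp <- max(lab)
  disc <- pi * (bead_diameter / 2 / pixel_size)^2
  cands <- list()
  for (k in seq_len(ncomp)) {
    idx <- which(lab == k, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < max(2, 0.2 * disc) || area > 4 * disc) next
    r0 <- max(1, min(idx[, 1]) - 3); r1 <- min(nrow(img), max(idx[, 1]) + 3)
    c0 <- max(1, min(idx[, 2]) - 3); c1 <- min(ncol(img), max(idx[, 2]) + 3)
    w <- pmax(sm[r0:r1, c0:c1] - 0.5 * thr, 0)
    if (sum(w) <= 0) next
    rr <- row(w) + r0 - 1; cc <- col(w) + c0 - 1
    u <- sum((cc - 1) * w) / sum(w)
    v <- sum((rr - 1) * w) / sum(w)
    cands[[length(cands) + 1]] <- data.frame(u = u, v = v, area = area)
  }
  out <- if (length(cands)) do.call(rbind, cands) else
    data.frame(u = numeric(0), v = numeric(0), area = numeric(0))
  if (nrow(out) != expected_count)
    stop_mrikin(sprintf("bead detection found %d candidates, expected %d",
                        nrow(out), expected_count),
                "mrikin_detection_error", candidates = out)
  out
}

# --- correspondence ----------------------------------------------------------

#' Assign detected centroids to grid bead labels
#'
#' Lattice orientation is resolved from the axis-marker beads when present
#' (falling back to principal axes of the cloud, which errors for the 4-fold
#' symmetric bare lattice), or taken from a previously resolved
#' `orientation` -- the scanner geometry is common to all plates, so the
#' orientation found on the marker-bearing plate is reused for the others.
#'
#' @param centroids data.frame with pixel columns `u`, `v`.
#' @param grid a `grid_spec`.
#' @param plate 0-based plate index (supplies the y coordinate and the
#'   expected axis beads).
#' @param orientation optional list with pixel-space unit vectors `x_dir`,
#'   `z_dir` (as returned in the result's `orientation` attribute).
#' @param handedness sign of det(\[x_dir z_dir\]) under the slice-axes
#'   convention; -1 for the canonical axial (y-normal) acquisition. Used only
#'   when a plate carries a single marker.
#' @return data.frame `label`, `u`, `v`, `x`, `y`, `z`, `axis_bead`, with the
#'   resolved `orientation` attached as an attribute.
#' @export
correspond_beads <- function(centroids, grid = grid_spec(), plate = 0L,
                             orientation = NULL, handedness = -1) {
  k <- grid$beads_per_side
  n_lattice <- k^2
  pts <- as.matrix(centroids[, c("u", "v")])
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  med_nn <- stats::median(nn)
  px_per_mm <- med_nn / grid$bead_spacing
  is_marker <- nn < 0.55 * med_nn
  if (sum(is_marker) > n - n_lattice) {
    # a marker's lattice neighbour is also flagged; keep the true outliers,
    # i.e. the points *not* on the lattice: markers are closer to their
    # neighbour than any two lattice points are to each other.
    flagged <- which(is_marker)
    keep_lattice <- rep(FALSE, n)
    for (i in flagged) {
      j <- which.min(D[i, ])
      # of the mutual pair, the lattice point has more neighbours at the pitch
      ni <- sum(abs(D[i, ] - med_nn) < 0.25 * med_nn)
      nj <- sum(abs(D[j, ] - med_nn) < 0.25 * med_nn)
      if (ni >= nj) keep_lattice[i] <- TRUE
    }
    is_marker[keep_lattice] <- FALSE
  }
  lattice_idx <- which(!is_marker)
  marker_idx <- which(is_marker)
  if (length(lattice_idx) != n_lattice)
    stop_mrikin(sprintf("could not isolate the %d lattice beads (%d found)",
                        n_lattice, length(lattice_idx)),
                "mrikin_correspondence_error")

  if (is.null(orientation)) {
    if (length(marker_idx) >= 1L) {
      corner_i <- lattice_idx[which.min(apply(
        D[lattice_idx, marker_idx, drop = FALSE], 1, min))]
      x_dir <- z_dir <- NULL
      for (mi in marker_idx) {
        d_mm <- D[corner_i, mi] / px_per_mm
        dir <- unit2(pts[corner_i, ] - pts[mi, ])
        if (abs(d_mm - 8) < abs(d_mm - 6)) x_dir <- dir else z_dir <- dir
      }
      if (is.null(x_dir) && !is.null(z_dir))
        x_dir <- if (handedness > 0) c(z_dir[2], -z_dir[1]) else c(-z_dir[2], z_dir[1])
      if (is.null(z_dir))
        z_dir <- if (handedness > 0) c(-x_dir[2], x_dir[1]) else c(x_dir[2], -x_dir[1])
      orientation <- list(x_dir = x_dir, z_dir = z_dir)
    } else {
      ev <- eigen(stats::cov(pts[lattice_idx, , drop = FALSE]))
      if (ev$values[2] / ev$values[1] > 0.9)
        stop_mrikin("lattice orientation is ambiguous (4-fold symmetric cloud, no axis beads)",
                    "mrikin_correspondence_error")
      x_dir <- unit2(ev$vectors[, 1])
      z_dir <- if (handedness > 0) c(-x_dir[2], x_dir[1]) else c(x_dir[2], -x_dir[1])
      orientation <- list(x_dir = x_dir, z_dir = z_dir)
    }
  }

  lp <- pts[lattice_idx, , drop = FALSE]
  px <- lp %*% orientation$x_dir
  pz <- lp %*% orientation$z_dir
  row_of <- rank_into_groups(px, k)
  col_of <- rank_into_groups(pz, k)
  if (anyDuplicated(paste(row_of, col_of)))
    stop_mrikin("row/column assignment is not bijective", "mrikin_correspondence_error")
  off <- (seq_len(k) - 1 - (k - 1) / 2) * grid$bead_spacing
  out <- data.frame(label = sprintf("P%d_%d%d", plate, row_of, col_of),
                    u = lp[, 1], v = lp[, 2],
                    x = off[row_of + 1], y = plate * grid$plate_spacing,
                    z = off[col_of + 1], axis_bead = FALSE)

  if (length(marker_idx)) {
    # fit an affine map world->pixel from the lattice and identify each
    # marker with its nearest expected axis-bead position
    fit_u <- stats::lm.fit(cbind(1, out$x, out$z), out$u)$coefficients
    fit_v <- stats::lm.fit(cbind(1, out$x, out$z), out$v)$coefficients
    ax <- grid_bead_coordinates(grid)
    ax <- ax[ax$axis_bead & ax$plate == plate, , drop = FALSE]
    for (mi in marker_idx) {
      if (nrow(ax) == 0) break
      pu <- fit_u[1] + fit_u[2] * ax$x + fit_u[3] * ax$z
      pv <- fit_v[1] + fit_v[2] * ax$x + fit_v[3] * ax$z
      d <- sqrt((pu - pts[mi, 1])^2 + (pv - pts[mi, 2])^2)
      j <- which.min(d)
      if (d[j] / px_per_mm < 3) {
        out <- rbind(out, data.frame(label = ax$label[j], u = pts[mi, 1],
                                     v = pts[mi, 2], x = ax$x[j], y = ax$y[j],
                                     z = ax$z[j], axis_bead = TRUE))
        ax <- ax[-j, , drop = FALSE]
      }
    }
  }
  attr(out, "orientation") <- orientation
  out
}

unit2 <- function(v) v / sqrt(sum(v^2))

rank_into_groups <- function(p, k) {
  ord <- order(p)
  g <- integer(length(p))
  g[ord] <- rep(seq_len(k) - 1L, each = length(p) / k)
  g
}

# --- planar DLT --------------------------------------------------------------

#' Fit the plane-to-image projective mapping of one plate
#'
#' Least-squares homography from world in-plane coordinates (x, z) to pixel
#' (u, v) with Hartley-style coordinate normalization; the stored normalized
#' coefficient vector has unit Frobenius norm, so every stored coefficient
#' has magnitude <= 1.
#'
#' @param corresponded data.frame with columns `x`, `z`, `u`, `v` (>= 4
#'   non-collinear correspondences).
#' @param plate plate index recorded in the result.
#' @return object of class `plate_mapping`: `H` (3x3, `H[3,3] = 1`),
#'   `coefficients` (normalized-space, magnitude <= 1), `rms_residual`
#'   (pixels), `plate`, `points`.
#' @export
fit_plate_mapping <- function(corresponded, plate = corresponded$plate[1] %||% 0L) {
  w <- cbind(corresponded$x, corresponded$z)
  p <- cbind(corresponded$u, corresponded$v)
  n <- nrow(w)
  if (is.null(n) || n < 4)
    stop_mrikin("at least 4 correspondences are required", "mrikin_fit_error")
  if (svd(scale(w, scale = FALSE))$d[2] < 1e-8 * max(1, svd(scale(w, scale = FALSE))$d[1]))
    stop_mrikin("control points are collinear", "mrikin_fit_error")
  Tw <- hartley_transform(w)
  Tp <- hartley_transform(p)
  wn <- apply_h2(Tw, w)
  pn <- apply_h2(Tp, p)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- c(wn[i, 1], wn[i, 2], 1)
    A[2 * i - 1, ] <- c(rep(0, 3), -X, pn[i, 2] * X)
    A[2 * i, ] <- c(X, rep(0, 3), -pn[i, 1] * X)
  }
  h <- svd(A)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  coefficients <- Hn / sqrt(sum(Hn^2))
  H <- solve(Tp) %*% Hn %*% Tw
  if (abs(H[3, 3]) < 1e-12)
    stop_mrikin("degenerate homography", "mrikin_fit_error")
  H <- H / H[3, 3]
  proj <- apply_h2(H, w)
  res <- sqrt(mean((proj - p)^2) * 2)  # rms over point distances
  structure(list(H = H, coefficients = coefficients, rms_residual = res,
                 plate = plate, points = corresponded),
            class = "plate_mapping")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hartley_transform <- function(x) {
  ctr <- colMeans(x)
  d <- sqrt(rowSums(sweep(x, 2, ctr)^2))
  s <- sqrt(2) / max(mean(d), 1e-12)
  matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
}

apply_h2 <- function(H, x) {
  xh <- cbind(x, 1) %*% t(H)
  xh[, 1:2, drop = FALSE] / xh[, 3]
}

#' @export
print.plate_mapping <- function(x, ...) {
  cat(sprintf("Plate %s homography: rms residual %.4g px over %d beads\n",
              x$plate, x$rms_residual, nrow(x$points)))
  invisible(x)
}

# --- assembled volume mapping ------------------------------------------------

#' Assemble the calibrated image/world volume mapping
#'
#' Fits a single affine-orthographic model u = A (x, z) + b across all plate
#' correspondences; the known plate spacing supplies the out-of-plane (y)
#' scale. This is the serialized calibration product that recreates the
#' imaging volume for registration.
#'
#' @param plates list of `plate_mapping` objects (>= 2).
#' @param grid the `grid_spec` used.
#' @param nominal_pixel_size the pixel size the calibration scans nominally
#'   claim (their sidecar value); the ratio of the recovered to the nominal
#'   size is the `scale_correction` applied when predicting cross-sections
#'   for any imaging protocol through this mapping.
#' @return object of class `volume_mapping` with `A` (2x2, px/mm), `b`,
#'   `Ainv`, `pixel_size_mm` (geometric mean world-per-pixel scale),
#'   `scale_correction`, `plate_spacing`, `rms_residual_mm` (global),
#'   `per_plate_rms_mm`.
#' @export
assemble_volume_mapping <- function(plates, grid = grid_spec(),
                                    nominal_pixel_size = 200 / 256) {
  if (length(plates) < 2)
    stop_mrikin("at least 2 fitted plates are required", "mrikin_calibration_error")
  pts <- do.call(rbind, lapply(plates, function(p)
    cbind(p$points[, c("x", "z", "u", "v")], plate = p$plate)))
  X <- cbind(1, pts$x, pts$z)
  cu <- stats::lm.fit(X, pts$u)$coefficients
  cv <- stats::lm.fit(X, pts$v)$coefficients
  A <- unname(rbind(c(cu[2], cu[3]), c(cv[2], cv[3])))
  b <- unname(c(cu[1], cv[1]))
  if (abs(det(A)) < 1e-12)
    stop_mrikin("degenerate volume mapping", "mrikin_calibration_error")
  Ainv <- solve(A)
  pixel_size <- 1 / sqrt(abs(det(A)))
  res_px <- cbind(pts$u - (X %*% cu), pts$v - (X %*% cv))
  res_mm <- res_px %*% t(Ainv)
  per_plate <- vapply(split(seq_len(nrow(pts)), pts$plate), function(i)
    sqrt(mean(rowSums(res_mm[i, , drop = FALSE]^2))), numeric(1))
  if (any(per_plate > 1))
    stop_mrikin(sprintf("inconsistent plate mappings (worst residual %.3g mm)",
                        max(per_plate)), "mrikin_calibration_error")
  structure(list(A = A, b = b, Ainv = Ainv, pixel_size_mm = pixel_size,
                 scale_correction = pixel_size / nominal_pixel_size,
                 plate_spacing = grid$plate_spacing,
                 rms_residual_mm = sqrt(mean(rowSums(res_mm^2))),
                 per_plate_rms_mm = per_plate,
                 n_points = nrow(pts)),
            class = "volume_mapping")
}

#' An exactly calibrated mapping (for synthetic scenes and testing)
#' @param pixel_size mm per pixel.
#' @param matrix image size in pixels.
#' @export
identity_volume_mapping <- function(pixel_size = 200 / 256, matrix = c(256, 256)) {
  s <- 1 / pixel_size
  cu <- (matrix[1] - 1) / 2; cv <- (matrix[2] - 1) / 2
  A <- diag(c(-s, s))  # axial convention: eu = -x, ev = +z
  structure(list(A = A, b = c(cu, cv), Ainv = solve(A),
                 pixel_size_mm = pixel_size, scale_correction = 1,
                 plate_spacing = 30, rms_residual_mm = 0,
                 per_plate_rms_mm = numeric(0), n_points = 0L),
            class = "volume_mapping")
}

#' Map between pixel and world coordinates of the calibrated volume
#'
#' With `y`/plate given, the grid-slice convention is used: (u, v) = A (x, z)
#' + b with y passed through (linearly interpolated between plates by
#' construction). For an arbitrary slice plane pass a `slice_spec`; the plane
#' placement comes from the `slice_spec` and the calibrated pixel scale from
#' the mapping.
#'
#' @param vm a `volume_mapping`.
#' @param world n x 3 matrix of world points, mm.
#' @return for `pixel_from_world`, an n x 3 matrix (u, v, y); for
#'   `world_from_pixel`, an n x 3 matrix (x, y, z).
#' @export
pixel_from_world <- function(vm, world) {
  world <- rbind_matrix3(world)
  uv <- sweep(world[, c(1, 3), drop = FALSE] %*% t(vm$A), 2, vm$b, "+")
  cbind(u = uv[, 1], v = uv[, 2], y = world[, 2])
}

#' @rdname pixel_from_world
#' @param pixel n x 2 matrix of (u, v) pixel coordinates.
#' @param y out-of-plane world coordinate(s) of the slice(s).
#' @export
world_from_pixel <- function(vm, pixel, y = 0) {
  pixel <- matrix(pixel, ncol = 2)
  xz <- sweep(pixel, 2, vm$b) %*% t(vm$Ainv)
  cbind(x = xz[, 1], y = y, z = xz[, 2])
}

rbind_matrix3 <- function(x) if (is.null(dim(x))) matrix(x, ncol = 3) else x

#' @export
print.volume_mapping <- function(x, ...) {
  cat(sprintf("Volume mapping: pixel size %.5f mm, global rms %.4g mm (%d beads)\n",
              x$pixel_size_mm, x$rms_residual_mm, x$n_points))
  invisible(x)
}

# --- end-to-end calibration --------------------------------------------------

#' Calibrate the imaging volume from grid slice images
#'
#' Runs detection, correspondence (orientation resolved on the first
#' marker-bearing plate and reused), per-plate homography fits and the
#' volume assembly.
#'
#' @param images list of grid slice images, one per plate (plate order).
#' @param grid a `grid_spec`.
#' @param pixel_size nominal pixel size used only for the detection size
#'   filter.
#' @return list with `mapping` (`volume_mapping`), `plates` (list of
#'   `plate_mapping`), `correspondences`.
#' @export
calibrate_volume <- function(images, grid = grid_spec(), pixel_size = 200 / 256) {
  ax <- axis_bead_table(grid)
  orientation <- NULL
  corrs <- list(); fits <- list()
  for (p in seq_along(images) - 1L) {
    expected <- grid$beads_per_side^2 + sum(ax$plate == p)
    cent <- tryCatch(
      detect_bead_centroids(images[[p + 1]], expected, pixel_size,
                            grid$bead_diameter),
      mrikin_detection_error = function(e)
        stop_mrikin(sprintf("plate %d: %s", p, conditionMessage(e)),
                    "mrikin_detection_error"))
    corr <- correspond_beads(cent, grid, plate = p, orientation = orientation)
    if (is.null(orientation)) orientation <- attr(corr, "orientation")
    corr$plate <- p
    corrs[[p + 1]] <- corr
    fits[[p + 1]] <- fit_plate_mapping(corr, plate = p)
  }
  list(mapping = assemble_volume_mapping(fits, grid), plates = fits,
       correspondences = corrs)
}

#' Serialize a volume mapping
#'
#' CSV (one row per named coefficient, mirroring the camera-file idea) or
#' JSON round trip.
#' @param vm a `volume_mapping`.
#' @param path output file.
#' @export
volume_mapping_write_csv <- function(vm, path) {
  df <- data.frame(
    name = c("a11", "a12", "a21", "a22", "b1", "b2", "pixel_size_mm",
             "plate_spacing_mm", "rms_residual_mm"),
    value = c(vm$A[1, 1], vm$A[1, 2], vm$A[2, 1], vm$A[2, 2], vm$b,
              vm$pixel_size_mm, vm$plate_spacing, vm$rms_residual_mm))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname volume_mapping_write_csv
#' @export
volume_mapping_write_json <- function(vm, path) {
  jsonlite::write_json(list(A = as.numeric(t(vm$A)), b = vm$b,
                            pixel_size_mm = vm$pixel_size_mm,
                            scale_correction = vm$scale_correction,
                            plate_spacing = vm$plate_spacing,
                            rms_residual_mm = vm$rms_residual_mm,
                            per_plate_rms_mm = vm$per_plate_rms_mm,
                            n_points = vm$n_points),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname volume_mapping_write_csv
#' @export
volume_mapping_read_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- matrix(as.numeric(x$A), 2, 2, byrow = TRUE)
  structure(list(A = A, b = as.numeric(x$b), Ainv = solve(A),
                 pixel_size_mm = x$pixel_size_mm,
                 scale_correction = x$scale_correction %||% 1,
                 plate_spacing = x$plate_spacing,
                 rms_residual_mm = x$rms_residual_mm,
                 per_plate_rms_mm = as.numeric(x$per_plate_rms_mm),
                 n_points = as.integer(x$n_points)),
            class = "volume_mapping")
}
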