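# Shared fixtures, all generated in code.

# Rendered calibration-grid slice images, one per plate.
make_grid_images <- function(grid = grid_spec(), seed = 100,
                             noise_sigma = NULL) {
  beads <- grid_bead_coordinates(grid)
  lapply(seq_len(grid$n_plates) - 1L, function(p) {
    spec <- grid_slice_spec(p, grid)
    if (!is.null(noise_sigma)) spec$noise_sigma <- noise_sigma
    pb <- beads[beads$plate == p, ]
    scene <- lapply(seq_len(nrow(pb)), function(i)
      list(solid = sphere_solid(grid$bead_diameter,
                                center = c(pb$x[i], pb$y[i], pb$z[i])),
           pose = rigid_pose()))
    render_slice(scene, spec, seed = seed + p)
  })
}

# Exact projected bead pixel coordinates (the digitization ground truth),
# per plate, under the canonical axial acquisition convention.
exact_grid_correspondences <- function(grid = grid_spec()) {
  beads <- grid_bead_coordinates(grid)
  vm <- identity_volume_mapping()
  lapply(seq_len(grid$n_plates) - 1L, function(p) {
    pb <- beads[beads$plate == p, ]
    px <- pixel_from_world(vm, cbind(pb$x, pb$y, pb$z))
    data.frame(label = pb$label, u = px[, 1], v = px[, 2],
               x = pb$x, y = pb$y, z = pb$z, plate = p,
               axis_bead = pb$axis_bead)
  })
}

# A random valid pose drawn from the current RNG stream.
random_pose <- function(t_scale = 30, angle_scale = 40) {
  R <- rot_x(stats::runif(1, -angle_scale, angle_scale)) %*%
    rot_y(stats::runif(1, -angle_scale, angle_scale)) %*%
    rot_z(stats::runif(1, -angle_scale, angle_scale))
  rigid_pose(R, stats::runif(3, -t_scale, t_scale))
}

expect_pose_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$rotation - b$rotation)), tol)
  expect_lt(max(abs(a$translation - b$translation)), tol)
}
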