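test_that("bead centroids are detected to sub-pixel accuracy", {
  grid <- grid_spec()
  truth <- exact_grid_correspondences(grid)[[3]]  # marker-free plate
  imgs <- make_grid_images(grid, noise_sigma = 0)
  cent <- detect_bead_centroids(imgs[[3]], 16)
  expect_equal(nrow(cent), 16)
  # match detected to truth by nearest neighbour
  err <- vapply(seq_len(16), function(i) {
    min(sqrt((cent$u - truth$u[i])^2 + (cent$v - truth$v[i])^2))
  }, numeric(1))
  expect_lt(max(err), 0.1)

  noisy <- make_grid_images(grid, seed = 7, noise_sigma = 0.05)
  cn <- detect_bead_centroids(noisy[[3]], 16)
  errn <- vapply(seq_len(16), function(i) {
    min(sqrt((cn$u - truth$u[i])^2 + (cn$v - truth$v[i])^2))
  }, numeric(1))
  expect_lt(sqrt(mean(errn^2)), 0.3)
})

test_that("blank or miscounted images raise a detection error", {
  blank <- matrix(0, 256, 256)
  err <- tryCatch(detect_bead_centroids(blank, 16), condition = identity)
  expect_s3_class(err, "mrikin_detection_error")
  expect_equal(nrow(err$candidates), 0)
})

test_that("correspondence resolves labels via the axis beads", {
  grid <- grid_spec()
  truth <- exact_grid_correspondences(grid)
  # plate 0 (two markers): labels must match the simulator labels exactly
  cent0 <- truth[[1]][, c("u", "v")]
  corr <- correspond_beads(cent0, grid, plate = 0)
  m <- merge(corr, truth[[1]], by = "label")
  expect_equal(nrow(m), 18)
  expect_equal(m$u.x, m$u.y, tolerance = 1e-9)
  expect_equal(m$x.x, m$x.y)

  # rotating the acquisition by 90 degrees: markers still resolve it
  rot90 <- data.frame(u = 255 - cent0$v, v = cent0$u)
  corr90 <- correspond_beads(rot90, grid, plate = 0)
  m90 <- merge(corr90[, c("label", "x", "z")],
               truth[[1]][, c("label", "x", "z")], by = "label")
  expect_equal(m90$x.x, m90$x.y)
  expect_equal(m90$z.x, m90$z.y)

  # marker-free plate rotated 90 degrees: declared ambiguous
  cent2 <- truth[[3]][, c("u", "v")]
  rot2 <- data.frame(u = 255 - cent2$v, v = cent2$u)
  expect_error(correspond_beads(rot2, grid, plate = 2),
               class = "mrikin_correspondence_error")

  # but the orientation resolved on plate 0 carries over
  corr2 <- correspond_beads(rot2, grid, plate = 2,
                            orientation = attr(corr90, "orientation"))
  m2 <- merge(corr2[, c("label", "x", "z")],
              truth[[3]][, c("label", "x", "z")], by = "label")
  expect_equal(nrow(m2), 16)
  expect_equal(m2$x.x, m2$x.y)
})

test_that("plate homography recovers an exact similarity map", {
  grid <- grid_spec()
  truth <- exact_grid_correspondences(grid)[[1]]
  fit <- fit_plate_mapping(truth, plate = 0)
  expect_lt(fit$rms_residual, 1e-9)
  # recovered scale: px per mm
  scale <- sqrt(abs(det(fit$H[1:2, 1:2])))
  expect_equal(scale, 256 / 200, tolerance = 1e-9)
  # stored normalized coefficients bounded by 1
  expect_lte(max(abs(fit$coefficients)), 1)
  expect_error(fit_plate_mapping(truth[1:3, ]), class = "mrikin_fit_error")
  collinear <- truth[truth$x == -30 & !truth$axis_bead, ]
  expect_error(fit_plate_mapping(collinear), class = "mrikin_fit_error")
})

test_that("homography residuals scale with centroid noise", {
  grid <- grid_spec()
  truth <- exact_grid_correspondences(grid)[[3]]
  set.seed(99)
  rms <- replicate(100, {
    noisy <- truth
    noisy$u <- noisy$u + rnorm(nrow(noisy), 0, 0.2)
    noisy$v <- noisy$v + rnorm(nrow(noisy), 0, 0.2)
    fit_plate_mapping(noisy, plate = 2)$rms_residual
  })
  expect_true(all(rms > 0.05 & rms < 0.4))
})

test_that("the assembled volume mapping closes exactly on perfect plates", {
  grid <- grid_spec()
  truth <- exact_grid_correspondences(grid)
  fits <- lapply(seq_along(truth), function(i)
    fit_plate_mapping(truth[[i]], plate = i - 1L))
  vm <- assemble_volume_mapping(fits, grid)
  expect_lt(vm$rms_residual_mm, 1e-9)
  expect_equal(vm$pixel_size_mm, 200 / 256, tolerance = 1e-9)

  # a bead on plate 2 maps to its known pixel and back
  w <- c(-10, 60, 30)
  px <- pixel_from_world(vm, w)
  tru <- pixel_from_world(identity_volume_mapping(), w)
  expect_equal(as.numeric(px), as.numeric(tru), tolerance = 1e-9)
  back <- world_from_pixel(vm, px[, 1:2], y = px[, 3])
  expect_equal(as.numeric(back), w, tolerance = 1e-9)

  # y midway between plates passes through linearly (orthographic contract)
  mid <- world_from_pixel(vm, cbind(100, 100), y = 45)
  expect_equal(unname(mid[1, "y"]), 45)

  expect_error(assemble_volume_mapping(fits[1], grid),
               class = "mrikin_calibration_error")
})

test_that("end-to-end calibration from rendered scans recovers the geometry", {
  grid <- grid_spec()
  imgs <- make_grid_images(grid, seed = 55)
  cal <- calibrate_volume(imgs, grid)
  expect_lt(abs(cal$mapping$pixel_size_mm - 200 / 256) / (200 / 256), 0.005)
  expect_lt(cal$mapping$rms_residual_mm, 0.3)
  # bead positions recovered with error commensurate with detection noise
  expect_lt(max(cal$mapping$per_plate_rms_mm), 0.2)
  # serialization round trip
  f <- tempfile(fileext = ".json")
  volume_mapping_write_json(cal$mapping, f)
  vm2 <- volume_mapping_read_json(f)
  expect_equal(vm2$A, cal$mapping$A)
  expect_equal(vm2$pixel_size_mm, cal$mapping$pixel_size_mm)
})

test_that("calibration is invariant to bead renumbering", {
  grid <- grid_spec()
  truth <- exact_grid_correspondences(grid)
  fits1 <- lapply(seq_along(truth), function(i)
    fit_plate_mapping(truth[[i]], plate = i - 1L))
  shuffled <- lapply(truth, function(d) d[sample(nrow(d)), ])
  fits2 <- lapply(seq_along(shuffled), function(i)
    fit_plate_mapping(shuffled[[i]], plate = i - 1L))
  vm1 <- assemble_volume_mapping(fits1, grid)
  vm2 <- assemble_volume_mapping(fits2, grid)
  expect_equal(vm1$A, vm2$A, tolerance = 1e-9)
  expect_equal(vm1$b, vm2$b, tolerance = 1e-9)
})
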