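test_that("the cross-section template shares the simulator's operator", {
  solid <- cube_solid()
  pose <- rigid_pose(diag(3), c(0, 5, 3))
  spec <- t1_slice_spec(normal = c(1, 0, 0), noise_sigma = 0)
  sim <- render_slice(list(list(solid = solid, pose = pose)), spec,
                      noise = FALSE)
  tmpl <- model_cross_section(solid, pose, spec,
                              identity_volume_mapping(spec$pixel_size))
  expect_lt(max(abs(tmpl - sim)), 1e-9)
  expect_true(all(tmpl >= 0 & tmpl <= 1))
})

test_that("templates are equivariant to in-plane translations", {
  solid <- cube_solid()
  spec <- t1_slice_spec(normal = c(1, 0, 0), noise_sigma = 0)
  k <- 5L
  base <- model_cross_section(solid, rigid_pose(), spec)
  shift <- model_cross_section(solid,
                               rigid_pose(diag(3), c(0, 0, k * spec$pixel_size)),
                               spec)
  cols <- 60:190
  expect_lt(max(abs(shift[, cols - k] - base[, cols])), 1e-9)
})

test_that("a slab that misses the solid yields an empty flagged template", {
  spec <- t1_slice_spec(normal = c(1, 0, 0), noise_sigma = 0)
  tmpl <- model_cross_section(cube_solid(), rigid_pose(diag(3), c(100, 0, 0)),
                              spec)
  expect_true(attr(tmpl, "empty"))
})

test_that("match score behaves as a normalized correlation", {
  spec <- t1_slice_spec(normal = c(1, 0, 0), noise_sigma = 0)
  t1 <- model_cross_section(cube_solid(), rigid_pose(), spec)
  expect_equal(as.numeric(match_score(t1, t1)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(match_score(t1, max(t1) - t1)), -1, tolerance = 1e-12)
  flat <- matrix(0.5, nrow(t1), ncol(t1))
  s <- match_score(flat, t1)
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "degenerate"))
  expect_error(match_score(t1[1:10, 1:10], t1), class = "mrikin_score_error")
})

test_that("single frames register to sub-voxel accuracy", {
  neutral <- neutral_cube_poses()
  solid <- cube_solid()
  spec <- t1_slice_spec(normal = c(1, 0, 0), noise_sigma = 0)
  truth_b <- rigid_pose(diag(3), neutral$b$translation + c(0, 0, 7))
  obs <- render_slice(list(list(solid = solid, pose = neutral$a),
                           list(solid = solid, pose = truth_b)),
                      spec, noise = FALSE)
  # init at truth: stays there
  fr <- rotoscope_frame(obs, list(solid, solid), list(neutral$a, truth_b),
                        "tz", list(spec), restarts = 1)
  expect_false(fr$failed)
  expect_lt(abs(fr$poses[[2]]$translation[3] - truth_b$translation[3]), 1e-3)

  # init offset 3 mm: recovered within 0.1 mm
  init_b <- rigid_pose(diag(3), truth_b$translation + c(0, 0, -3))
  fr2 <- rotoscope_frame(obs, list(solid, solid), list(neutral$a, init_b),
                         "tz", list(spec), restarts = 2)
  expect_lt(abs(fr2$poses[[2]]$translation[3] - truth_b$translation[3]), 0.1)

  # rotation frame at 20 deg, init at 15 deg: within 0.5 deg
  rot_truth <- rigid_pose(rot_x(20), neutral$b$translation)
  obs_r <- render_slice(list(list(solid = solid, pose = neutral$a),
                             list(solid = solid, pose = rot_truth)),
                        spec, noise = FALSE)
  init_r <- rigid_pose(rot_x(15), neutral$b$translation)
  fr3 <- rotoscope_frame(obs_r, list(solid, solid), list(neutral$a, init_r),
                         "rx", list(spec), restarts = 2)
  ang <- euler_xyz(fr3$poses[[2]]$rotation)$angles[["x"]]
  expect_lt(abs(ang - 20), 0.5)
})

test_that("the match score falls monotonically away from the optimum", {
  neutral <- neutral_cube_poses()
  solid <- cube_solid()
  spec <- t1_slice_spec(normal = c(1, 0, 0), noise_sigma = 0)
  obs <- render_slice(list(list(solid = solid, pose = neutral$a),
                           list(solid = solid, pose = neutral$b)),
                      spec, noise = FALSE)
  score_at <- function(dz) {
    pb <- rigid_pose(diag(3), neutral$b$translation + c(0, 0, dz))
    tm <- render_scene_pair(solid, neutral$a, pb, spec)
    as.numeric(match_score(tm, obs))
  }
  render_scene_pair <- function(solid, pa, pb, spec) {
    ta <- model_cross_section(solid, pa, spec)
    tb <- model_cross_section(solid, pb, spec)
    pmin(ta + tb, 1)
  }
  s <- vapply(c(0, 0.5, 1, 2, 5), score_at, numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("injected perfect poses reproduce displacements exactly", {
  neutral <- neutral_cube_poses()
  b10 <- rigid_pose(diag(3), neutral$b$translation + c(0, 0, 10))
  fake <- structure(list(trial_type = "translation_z",
                         poses = list(list(neutral$a, neutral$b),
                                      list(neutral$a, b10)),
                         scores = c(1, 1), failed = c(FALSE, FALSE),
                         nominal = c(0, 10),
                         axes = default_joint_axes()),
                    class = "rotoscope")
  df <- extract_displacement_series(fake)
  expect_equal(df$measured, c(0, 10), tolerance = 1e-12)
})

test_that("a noiseless series registers within the optimizer tolerance", {
  s <- generate_trial_series("translation_z", c(0, 5, 10), n_per_level = 2,
                             noise_sigma = 0, seed = 3)
  r <- rotoscope_series(s, seed = 1)
  expect_false(any(r$failed))
  expect_lt(max(abs(r$displacements$measured - s$true_displacement[, 1])), 0.05)
  expect_s3_class(r, "rotoscope")
  expect_named(coef(r), c("frame_index", "nominal", "measured"))
})

test_that("the orthogonal view rescues the out-of-plane component", {
  s <- generate_trial_series("biplanar", c(0, 5, 10), n_per_level = 1,
                             imaging = "fast", noise_sigma = 0, seed = 6)
  both <- rotoscope_series(s, seed = 1)
  err_both <- max(abs(both$displacements$measured_x - s$true_displacement[, 2]))

  single <- s
  single$frames <- lapply(single$frames, function(f) f[1])
  single$slice_specs <- single$slice_specs[1]
  one <- rotoscope_series(single, dof_mask = "tz_tx", seed = 1)
  err_one <- max(abs(one$displacements$measured_x - s$true_displacement[, 2]))
  expect_lt(err_both, 0.7)
  expect_lte(err_both, err_one)
})

test_that("axes saved from one session drive the next", {
  s <- generate_trial_series("translation_z", c(0, 5), n_per_level = 1,
                             noise_sigma = 0, seed = 9)
  r1 <- rotoscope_series(s, seed = 1)
  f <- tempfile(fileext = ".json")
  axes_save(r1$axes, f)
  r2 <- rotoscope_series(s, axes = axes_load(f), seed = 2)
  expect_equal(r2$axes$origin, r1$axes$origin, tolerance = 1e-9)
  expect_equal(r2$displacements$measured, r1$displacements$measured,
               tolerance = 0.05)
})
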