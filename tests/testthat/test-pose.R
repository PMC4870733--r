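test_that("pose composition follows the matrix-product oracle", {
  p <- rigid_pose(rot_y(30), c(1, 2, 3))
  expect_pose_equal(compose_poses(rigid_pose(), p), p, 1e-12)
  expect_pose_equal(compose_poses(p, pose_inverse(p)), rigid_pose(), 1e-12)

  a <- rigid_pose(rot_x(10), c(0, 0, 5))
  b <- rigid_pose(rot_x(10), c(0, 0, 0))
  ab <- compose_poses(a, b)
  expect_lt(max(abs(ab$rotation - rot_x(20))), 1e-12)
  # independent check: apply to a point two ways
  x <- c(3, -4, 7)
  expect_equal(pose_apply(ab, x), pose_apply(a, pose_apply(b, x)),
               tolerance = 1e-12)
})

test_that("invalid rotations are rejected", {
  expect_error(rigid_pose(matrix(1, 3, 3), c(0, 0, 0)),
               class = "mrikin_pose_error")
  expect_error(rigid_pose(diag(c(1, 1, -1))), class = "mrikin_pose_error")
  bad <- rigid_pose()
  bad$rotation[1, 1] <- 2
  expect_error(compose_poses(bad, rigid_pose()), class = "mrikin_pose_error")
})

test_that("Euler x-y-z decomposition inverts on random rotations", {
  set.seed(42)
  for (i in 1:25) {
    ang <- stats::runif(3, -75, 75)
    R <- rot_x(ang[1]) %*% rot_y(ang[2]) %*% rot_z(ang[3])
    e <- euler_xyz(R)
    expect_false(e$gimbal)
    expect_equal(unname(e$angles), ang, tolerance = 1e-9)
  }
  expect_true(euler_xyz(rot_y(90))$gimbal)
})

test_that("JCS displacement reports pure translations and rotations", {
  n <- neutral_cube_poses()
  ax <- default_joint_axes()
  rec0 <- jcs_displacement(n$a, n$b, n$a, n$b, ax)
  expect_equal(max(abs(rec0$full_6dof)), 0, tolerance = 1e-12)

  b5 <- rigid_pose(diag(3), n$b$translation + c(0, 0, 5))
  rec <- jcs_displacement(n$a, n$b, n$a, b5, ax)
  expect_equal(rec$translation_z, 5, tolerance = 1e-12)
  expect_equal(rec$rotation_about_x, 0, tolerance = 1e-12)
  expect_equal(rec$translation_x, 0, tolerance = 1e-12)
})

test_that("rotation about a centre of rotation matches the explicit transform", {
  # moving body's COR 50 mm from the stationary body's centre
  n <- neutral_cube_poses()
  cor_pt <- n$b$translation
  expect_equal(sqrt(sum((cor_pt - n$a$translation)^2)), 50)
  rotpose <- pose_rotation_about(c(1, 0, 0), 20, center = cor_pt)
  b_cur <- compose_poses(rotpose, n$b)

  # axes at the COR: pure 20-degree rotation, no translation
  rec <- jcs_displacement(n$a, n$b, n$a, b_cur, joint_axes(origin = cor_pt))
  expect_equal(rec$rotation_about_x, 20, tolerance = 1e-9)
  expect_equal(abs(rec$translation_z), 0, tolerance = 1e-9)

  # axes elsewhere: the record's translation is the physical displacement of
  # the body-B-attached copy of the axes origin, (R - I)(o - c), computed
  # here independently from first principles
  o <- c(0, 0, 0)
  rec2 <- jcs_displacement(n$a, n$b, n$a, b_cur, joint_axes(origin = o))
  a <- 20 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  expected_t <- as.numeric((Rx - diag(3)) %*% (o - cor_pt))
  expect_equal(unname(rec2$full_6dof[c("tx", "ty", "tz")]), expected_t,
               tolerance = 1e-9)
  expect_equal(rec2$rotation_about_x, 20, tolerance = 1e-9)
})

test_that("displacement records round-trip back to the relative pose", {
  set.seed(7)
  ax <- joint_axes(origin = c(5, -3, 2))
  for (i in 1:20) {
    na <- random_pose(); nb <- random_pose()
    ca <- random_pose(); cb <- random_pose()
    rec <- jcs_displacement(na, nb, ca, cb, ax)
    if (rec$gimbal) next
    cb2 <- jcs_reconstruct_b(rec, na, nb, ca, ax)
    expect_pose_equal(cb2, cb, 1e-9)
  }
})

test_that("JCS displacement is invariant to a common world transform", {
  set.seed(8)
  ax <- joint_axes(origin = c(1, 2, 3))
  na <- random_pose(); nb <- random_pose()
  ca <- random_pose(); cb <- random_pose()
  rec <- jcs_displacement(na, nb, ca, cb, ax)
  g <- random_pose()
  gax <- joint_axes(origin = pose_apply(g, ax$origin),
                    x_axis = as.numeric(g$rotation %*% ax$rotation[, 1]),
                    y_axis = as.numeric(g$rotation %*% ax$rotation[, 2]),
                    z_axis = as.numeric(g$rotation %*% ax$rotation[, 3]))
  rec2 <- jcs_displacement(compose_poses(g, na), compose_poses(g, nb),
                           compose_poses(g, ca), compose_poses(g, cb), gax)
  expect_equal(rec$full_6dof, rec2$full_6dof, tolerance = 1e-9)
})

test_that("poses and axes serialize losslessly", {
  p <- rigid_pose(rot_z(33), c(0.1, -2, 7))
  expect_pose_equal(pose_from_list(pose_to_list(p)), p, 1e-15)
  ax <- joint_axes(origin = c(1, 2, 3), x_axis = c(0, 1, 0),
                   y_axis = c(-1, 0, 0), z_axis = c(0, 0, 1))
  f <- tempfile(fileext = ".json")
  axes_save(ax, f)
  ax2 <- axes_load(f)
  expect_equal(ax2$origin, ax$origin)
  expect_lt(max(abs(ax2$rotation - ax$rotation)), 1e-12)
})
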