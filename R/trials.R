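# Displacement trial designs and the simulated-rater session model.
#
# Study geometry: two bored cubes stacked along y (the coil bore axis, the
# stacking direction of vertebral bodies), centres 50 mm apart leaving a
# 10 mm inter-cube gap. The stationary cube A sits below, the moving cube B
# above. Single-plane trials are imaged in the mid-sagittal zy-plane (normal
# x); biplanar trials add an orthogonal xy-plane view (normal z).

#' Default neutral poses of the two cubes
#' @return list with poses `a` and `b`.
#' @export
neutral_cube_poses <- function() {
  list(a = rigid_pose(diag(3), c(0, -25, 0)),
       b = rigid_pose(diag(3), c(0, 25, 0)))
}

#' Default joint axes for the cube pair
#'
#' Origin at the moving cube's neutral centre, axes aligned with the world
#' (grid) frame, so rotation-trial records carry pure rotation about x and
#' translation-trial records pure translation along z.
#' @export
default_joint_axes <- function() joint_axes(origin = c(0, 25, 0))

trial_slice_specs <- function(trial_type, imaging) {
  base <- switch(imaging, t1 = t1_slice_spec, fast = fast_slice_spec,
                 stop_mrikin("unknown imaging spec", "mrikin_param_error"))
  sag <- base(origin = c(0, 0, 0), normal = c(1, 0, 0))
  if (trial_type == "biplanar")
    list(sag, base(origin = c(0, 0, 0), normal = c(0, 0, 1)))
  else list(sag)
}

# Pose of the moving cube for a nominal displacement of one trial family.
moving_pose <- function(trial_type, value_z, value_x = 0) {
  nb <- neutral_cube_poses()$b
  switch(trial_type,
    translation_z = rigid_pose(diag(3), nb$translation + c(0, 0, value_z)),
    rotation_x = rigid_pose(rot_x(value_z), nb$translation),
    biplanar = rigid_pose(diag(3), nb$translation + c(value_x, 0, value_z)),
    stop_mrikin("unknown trial_type", "mrikin_trial_error"))
}

#' Generate a displacement trial series with hidden ground truth
#'
#' Reproduces the study designs: translations 0-20 mm in 5 mm steps (7
#' replicates per level), rotations 0-20 degrees in 5 degree steps (6 per
#' level) about the x axis with the moving cube's centre 50 mm from the
#' stationary cube's centre, and biplanar z+x translations (4 per level, two
#' orthogonal slices per frame). Frame 0 is the neutral position (first
#' replicate of the zero level, no jitter); every other frame realizes its
#' nominal displacement plus a uniform placement jitter emulating manual
#' caliper positioning.
#'
#' @param trial_type "translation_z", "rotation_x" or "biplanar".
#' @param displacement_levels nominal levels (mm or degrees).
#' @param n_per_level replicates per level; defaults to the study design
#'   (7, 6, 4 for the three trial types).
#' @param imaging "t1" (0.78125 mm/5 mm) or "fast" (0.98 mm/8 mm).
#' @param jitter half-width of the uniform placement jitter (mm or deg).
#' @param seed integer seed governing jitter and image noise.
#' @param noise_sigma,blur_fwhm imaging overrides applied to every slice.
#' @param render render the slice images (set `FALSE` for ground-truth-only
#'   series, e.g. when exercising the statistics layer).
#' @return object of class `trial_series`: list with `trial_type`, `frames`
#'   (each: list of one or two images), `slice_specs`, `ground_truth`
#'   (per-frame pose pairs), `nominal` (per-frame nominal displacement;
#'   two-column matrix for biplanar), `true_displacement` (nominal + jitter),
#'   `neutral_poses`, `seed`.
#' @export
generate_trial_series <- function(trial_type = c("translation_z", "rotation_x", "biplanar"),
                                  displacement_levels = seq(0, 20, by = 5),
                                  n_per_level = NULL,
                                  imaging = c("t1", "fast"),
                                  jitter = 0.2, seed = 1,
                                  noise_sigma = NULL, blur_fwhm = NULL,
                                  render = TRUE) {
  trial_type <- match.arg(trial_type)
  imaging <- match.arg(imaging)
  if (length(displacement_levels) == 0)
    stop_mrikin("displacement_levels must be non-empty", "mrikin_trial_error")
  if (is.null(n_per_level))
    n_per_level <- switch(trial_type, translation_z = 7L, rotation_x = 6L,
                          biplanar = 4L)
  specs <- trial_slice_specs(trial_type, imaging)
  if (!is.null(noise_sigma)) specs <- lapply(specs, function(s) { s$noise_sigma <- noise_sigma; s })
  if (!is.null(blur_fwhm)) specs <- lapply(specs, function(s) { s$blur_fwhm <- blur_fwhm; s })
  design <- expand.grid(replicate = seq_len(n_per_level),
                        level = displacement_levels)
  design <- design[order(design$level, design$replicate), ]
  n <- nrow(design)
  neutral <- neutral_cube_poses()
  solid <- cube_solid()
  frames <- vector("list", n)
  frame_specs <- vector("list", n)
  gt <- vector("list", n)
  true_disp <- matrix(0, n, if (trial_type == "biplanar") 2L else 1L)
  jit <- with_seed(child_seed(seed, 0),
                   matrix(stats::runif(n * 2, -jitter, jitter), n, 2))
  for (i in seq_len(n)) {
    lev <- design$level[i]
    is_neutral <- (i == 1L)
    jz <- if (is_neutral) 0 else jit[i, 1]
    jx <- if (is_neutral) 0 else jit[i, 2]
    if (trial_type == "biplanar") {
      true_disp[i, ] <- c(lev + jz, lev + jx)
      pb <- moving_pose(trial_type, lev + jz, lev + jx)
    } else {
      true_disp[i, 1] <- lev + jz
      pb <- moving_pose(trial_type, lev + jz)
    }
    gt[[i]] <- list(a = neutral$a, b = pb)
    # biplanar slices are repositioned per trial (as the operator does) so
    # the cores of both cubes stay in view: each view's out-of-plane origin
    # follows the nominal displacement of its normal axis
    fspecs <- specs
    if (trial_type == "biplanar") {
      fspecs[[1]]$origin <- c(lev, 0, 0)   # normal-x view tracks nominal x
      fspecs[[2]]$origin <- c(0, 0, lev)   # normal-z view tracks nominal z
    }
    frame_specs[[i]] <- fspecs
    if (render) {
      frames[[i]] <- lapply(seq_along(fspecs), function(k)
        render_slice(list(list(solid = solid, pose = neutral$a),
                          list(solid = solid, pose = pb)),
                     fspecs[[k]], seed = child_seed(seed, i * 10 + k)))
    }
  }
  structure(list(trial_type = trial_type, imaging = imaging,
                 levels = displacement_levels, design = design,
                 frames = frames, slice_specs = specs,
                 frame_specs = frame_specs,
                 ground_truth = gt, nominal = design$level,
                 true_displacement = true_disp,
                 neutral_poses = neutral, solid = solid,
                 jitter = jitter, seed = seed),
            class = "trial_series")
}

#' @export
print.trial_series <- function(x, ...) {
  cat(sprintf("Trial series: %s (%s imaging), %d frames, levels %s, seed %d\n",
              x$trial_type, x$imaging, nrow(x$design),
              paste(x$levels, collapse = "/"), x$seed))
  invisible(x)
}

#' Simulate a pair of rater sessions
#'
#' Stands in for the human rater: each session measures the true values with
#' an additive rater bias and independent Gaussian error, `measurement =
#' true + bias + N(0, sigma^2)`, independently per session and trial.
#'
#' @param true_values vector of true displacements (mm or deg).
#' @param rater_bias systematic offset.
#' @param rater_sigma per-measurement error SD (>= 0).
#' @param bias_mode "both" applies the bias to both sessions (pure random
#'   disagreement); "session2" applies it to session 2 only (systematic
#'   between-session bias).
#' @param seed integer seed.
#' @return list with `session1`, `session2`, `true_values`.
#' @export
simulate_session_pair <- function(true_values, rater_bias = 0, rater_sigma = 0.4,
                                  bias_mode = c("both", "session2"), seed = 1) {
  bias_mode <- match.arg(bias_mode)
  if (rater_sigma < 0) stop_mrikin("rater_sigma must be >= 0", "mrikin_param_error")
  n <- length(true_values)
  e <- with_seed(seed, matrix(stats::rnorm(2 * n, 0, rater_sigma), n, 2))
  b1 <- if (bias_mode == "both") rater_bias else 0
  list(session1 = true_values + b1 + e[, 1],
       session2 = true_values + rater_bias + e[, 2],
       true_values = true_values)
}
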