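# Automated rotoscoping: render a posed solid's thick-slab cross-section
# through the calibrated mapping, score it against the observed slice by
# zero-normalized cross-correlation, and maximize the score over the degrees
# of freedom allowed by the trial physics with a derivative-free search.
#
# The manual model-to-outline matching of the original workflow is
# operationalized as NCC maximization: reproducible, derivative-free like a
# human, and testable. No claim is made that it reproduces a human rater's
# error distribution.

#' Predicted cross-section template of a posed solid
#'
#' Shares the simulator's partial-volume rendering operator, but the pixel
#' scale comes from the calibrated `volume_mapping` rather than the nominal
#' spec (the plane placement still comes from the slice sidecar).
#'
#' @param solid a `mrikin_solid`.
#' @param pose a `rigid_pose`.
#' @param spec the `slice_spec` of the target image.
#' @param mapping a `volume_mapping`, or `NULL` for the nominal spec scale.
#' @return matrix on the target pixel grid, values in \[0, 1\]; attribute
#'   `"empty"` flags a slab that misses the solid.
#' @export
model_cross_section <- function(solid, pose, spec, mapping = NULL) {
  px <- if (is.null(mapping)) NULL else spec$pixel_size * mapping$scale_correction
  render_scene(list(list(solid = solid, pose = pose)), spec, pixel_size = px)
}

#' Zero-normalized cross-correlation match score
#'
#' 1 is a perfect match, -1 a perfect inversion; a constant template or image
#' scores 0 with a `"degenerate"` attribute.
#' @param template predicted cross-section (same pixel grid as `observed`).
#' @param observed observed slice image.
#' @export
match_score <- function(template, observed) {
  if (!all(dim(template) == dim(observed)))
    stop_mrikin("template and image are on different pixel grids",
                "mrikin_score_error")
  a <- as.numeric(template) - mean(template)
  b <- as.numeric(observed) - mean(observed)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12)
    return(structure(0, degenerate = TRUE))
  sum(a * b) / (na * nb)
}

# DOF masks: which pose parameters of each body the optimizer may move.
dof_params <- function(dof_mask) {
  switch(dof_mask,
         tz = c("tz"),
         rx = c("rx"),
         tz_tx = c("tz", "tx"),
         six = c("tx", "ty", "tz", "rx", "ry", "rz"),
         stop_mrikin("unknown dof_mask", "mrikin_param_error"))
}

# Apply masked parameters to a reference pose. Rotations are about the body's
# own centre (pre-multiplied), translations along world axes.
apply_dof <- function(ref, par, names) {
  t_ <- ref$translation
  R <- ref$rotation
  rx <- ry <- rz <- 0
  for (i in seq_along(names)) {
    v <- par[i]
    switch(names[i],
           tx = t_[1] <- t_[1] + v,
           ty = t_[2] <- t_[2] + v,
           tz = t_[3] <- t_[3] + v,
           rx = rx <- v, ry = ry <- v, rz = rz <- v)
  }
  if (rx != 0 || ry != 0 || rz != 0)
    R <- euler_to_rotation(c(rx, ry, rz)) %*% R
  rigid_pose(R, t_)
}

score_poses <- function(par, refs, solids, specs, observed, mapping, dnames) {
  npar <- length(dnames)
  rot_excess <- 0
  poses <- vector("list", length(solids))
  for (j in seq_along(solids)) {
    pj <- par[((j - 1) * npar + 1):(j * npar)]
    rot <- pj[dnames %in% c("rx", "ry", "rz")]
    rot_excess <- rot_excess + sum(pmax(0, abs(rot) - 45))
    pj[dnames %in% c("rx", "ry", "rz")] <- pmax(-45, pmin(45, rot))
    poses[[j]] <- apply_dof(refs[[j]], pj, dnames)
  }
  sc <- 0
  for (k in seq_along(observed)) {
    px <- if (is.null(mapping)) NULL else
      specs[[k]]$pixel_size * mapping$scale_correction
    tmpl <- render_scene(lapply(seq_along(solids), function(j)
      list(solid = solids[[j]], pose = poses[[j]])), specs[[k]],
      pixel_size = px)
    sc <- sc + as.numeric(match_score(tmpl, observed[[k]]))
  }
  list(score = sc / length(observed) - 0.1 * rot_excess, poses = poses)
}

#' Register the solids to one frame's slice image(s)
#'
#' Nelder-Mead maximization of the (view-averaged) match score over the
#' concatenated masked DOFs of all bodies, with seeded jittered restarts.
#' Rotation parameters are clamped to +/-45 degrees to avoid the bored cube's
#' 90-degree symmetry basin.
#'
#' @param observed list of one (single-plane) or two (biplanar) slice images.
#' @param solids list of solids (stationary first, moving second).
#' @param init_poses list of initial poses, one per solid; must be within the
#'   capture range (about +/-10 mm / +/-20 deg) of the truth. In series mode
#'   the previous frame provides this.
#' @param dof_mask one of "tz", "rx", "tz_tx", "six".
#' @param specs list of `slice_spec`s matching `observed`.
#' @param mapping a `volume_mapping` (or `NULL` for nominal scale).
#' @param restarts number of jittered restarts.
#' @param jitter restart jitter half-widths, `c(mm, deg)`.
#' @param fail_score score below which the frame is declared failed.
#' @param early_score stop restarting once this score is reached.
#' @param seed integer seed for the restart jitter.
#' @return list with `poses`, `score`, `failed`, `iterations`,
#'   `restarts_used`.
#' @export
rotoscope_frame <- function(observed, solids, init_poses, dof_mask, specs,
                            mapping = NULL, restarts = 5, jitter = c(2, 5),
                            fail_score = 0.5, early_score = 0.97, seed = 1) {
  if (!is.list(observed)) observed <- list(observed)
  dnames <- dof_params(dof_mask)
  npar <- length(dnames)
  ntot <- npar * length(solids)
  is_rot <- rep(dnames %in% c("rx", "ry", "rz"), times = length(solids))
  fn <- function(par) -score_poses(par, init_poses, solids, specs, observed,
                                   mapping, dnames)$score
  best <- NULL; iters <- 0L; used <- 0L
  starts <- with_seed(seed, {
    s <- matrix(stats::runif(restarts * ntot, -1, 1), restarts, ntot)
    s[1, ] <- 0
    s
  })
  for (r in seq_len(restarts)) {
    p0 <- starts[r, ] * ifelse(is_rot, jitter[2], jitter[1])
    opt <- stats::optim(p0, fn, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 400))
    used <- used + 1L
    iters <- iters + opt$counts[1]
    if (is.null(best) || opt$value < best$value) best <- opt
    if (-best$value >= early_score) break
  }
  # polish: restart the simplex at the incumbent until it stops improving,
  # guarding against premature simplex collapse
  for (p in 1:3) {
    opt <- stats::optim(best$par, fn, method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 400))
    iters <- iters + opt$counts[1]
    if (opt$value < best$value - 1e-8) best <- opt else break
  }
  final <- score_poses(best$par, init_poses, solids, specs, observed,
                       mapping, dnames)
  list(poses = final$poses, score = final$score,
       failed = final$score < fail_score,
       iterations = as.integer(iters), restarts_used = used,
       par = best$par)
}

#' Rotoscope a full trial series
#'
#' Frames are processed in order; each is initialized at the previous
#' successful frame's solution (the neutral frame at the series' designed
#' neutral poses). The anatomical joint axes are fixed at the registered
#' neutral frame -- pass `axes` to reuse the axes saved from another session
#' (see [axes_save()]).
#'
#' @param series a `trial_series` (images and specs; ground truth is never
#'   consulted).
#' @param solids list of the two solid models; defaults to the series' cube
#'   geometry.
#' @param mapping a `volume_mapping` (or `NULL` for the nominal pixel scale).
#' @param dof_mask DOF mask; defaults to the trial physics ("tz" for
#'   translation, "rx" for rotation, "tz_tx" for biplanar).
#' @param axes `joint_axes` to reuse; by default assigned at the registered
#'   neutral frame (origin at the moving body's centre, world-aligned axes).
#' @param seed seed for the optimizer restarts.
#' @param ... passed to [rotoscope_frame()].
#' @return object of class `rotoscope`: per-frame poses, scores,
#'   convergence diagnostics, the joint axes used, and the extracted
#'   displacement table.
#' @export
rotoscope_series <- function(series, solids = NULL, mapping = NULL,
                             dof_mask = NULL, axes = NULL, seed = 1, ...) {
  if (is.null(solids)) solids <- list(series$solid, series$solid)
  if (is.null(dof_mask))
    dof_mask <- switch(series$trial_type, translation_z = "tz",
                       rotation_x = "rx", biplanar = "tz_tx")
  n <- length(series$frames)
  poses <- vector("list", n)
  scores <- numeric(n); failed <- logical(n)
  iterations <- integer(n); restarts_used <- integer(n)
  init <- list(series$neutral_poses$a, series$neutral_poses$b)
  last_good <- init
  for (i in seq_len(n)) {
    specs_i <- series$frame_specs[[i]] %||% series$slice_specs
    fr <- rotoscope_frame(series$frames[[i]], solids, last_good, dof_mask,
                          specs_i, mapping,
                          seed = child_seed(seed, i), ...)
    poses[[i]] <- fr$poses
    scores[i] <- fr$score; failed[i] <- fr$failed
    iterations[i] <- fr$iterations; restarts_used[i] <- fr$restarts_used
    if (i == 1L && fr$failed)
      stop_mrikin(sprintf("neutral frame failed to register (score %.3f)", fr$score),
                  "mrikin_registration_error")
    if (!fr$failed) last_good <- fr$poses
  }
  if (is.null(axes))
    axes <- joint_axes(origin = poses[[1]][[2]]$translation)
  out <- structure(list(trial_type = series$trial_type, poses = poses,
                        scores = scores, failed = failed,
                        iterations = iterations,
                        restarts_used = restarts_used,
                        axes = axes, nominal = series$nominal,
                        dof_mask = dof_mask, seed = seed,
                        call = match.call()),
                   class = "rotoscope")
  out$displacements <- extract_displacement_series(out)
  out
}

#' Extract joint-coordinate-system displacements from a registration
#'
#' Per-frame [jcs_displacement()] of the registered poses against the
#' registered neutral frame, plus the trial-appropriate single-plane scalar
#' (`measured`; for biplanar trials `measured` is translation z and
#' `measured_x` translation x).
#'
#' @param result a `rotoscope` object (or a compatible list of per-frame
#'   pose pairs in `$poses`).
#' @param axes joint axes; defaults to the axes stored in `result`.
#' @return data.frame with one row per frame.
#' @export
extract_displacement_series <- function(result, axes = result$axes) {
  na <- result$poses[[1]][[1]]; nb <- result$poses[[1]][[2]]
  rows <- lapply(seq_along(result$poses), function(i) {
    rec <- jcs_displacement(na, nb, result$poses[[i]][[1]],
                            result$poses[[i]][[2]], axes, frame_index = i - 1L)
    as.data.frame(rec)
  })
  df <- do.call(rbind, rows)
  df$score <- result$scores
  df$failed <- result$failed
  df$measured <- switch(result$trial_type %||% "translation_z",
                        rotation_x = df$rotation_about_x,
                        df$translation_z)
  if (identical(result$trial_type, "biplanar")) df$measured_x <- df$translation_x
  if (!is.null(result$nominal)) df$nominal <- result$nominal
  df
}

#' @export
print.rotoscope <- function(x, ...) {
  cat(sprintf("Rotoscoped %s series: %d frames, dof mask '%s'\n",
              x$trial_type, length(x$poses), x$dof_mask))
  cat(sprintf("  scores: min %.3f / mean %.3f; %d failed frame(s)\n",
              min(x$scores), mean(x$scores), sum(x$failed)))
  invisible(x)
}

#' @export
summary.rotoscope <- function(object, ...) {
  df <- object$displacements
  cat(sprintf("Rotoscope summary (%s, %d frames):\n", object$trial_type,
              nrow(df)))
  print(utils::head(df[, intersect(c("frame_index", "nominal", "measured",
                                     "measured_x", "score"), names(df))], 10))
  if (nrow(df) > 10) cat("  ...\n")
  invisible(df)
}

#' @export
coef.rotoscope <- function(object, ...) {
  cols <- intersect(c("frame_index", "nominal", "measured", "measured_x"),
                    names(object$displacements))
  object$displacements[, cols]
}

#' @export
plot.rotoscope <- function(x, ...) {
  df <- x$displacements
  graphics::plot(df$nominal, df$measured,
                 xlab = sprintf("nominal displacement (%s)",
                                if (x$trial_type == "rotation_x") "deg" else "mm"),
                 ylab = "measured displacement",
                 main = sprintf("Rotoscoped %s recovery", x$trial_type), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Write per-frame registration results to CSV
#' @param result a `rotoscope` object.
#' @param path output CSV path.
#' @export
rotoscope_write_csv <- function(result, path) {
  rows <- lapply(seq_along(result$poses), function(i) {
    do.call(rbind, lapply(seq_along(result$poses[[i]]), function(j) {
      p <- result$poses[[i]][[j]]
      data.frame(frame = i - 1L, body = c("a", "b")[j],
                 score = result$scores[i],
                 t(stats::setNames(p$translation, c("tx", "ty", "tz"))),
                 t(stats::setNames(as.numeric(t(p$rotation)),
                                   paste0("r", rep(1:3, each = 3), rep(1:3, 3)))))
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read poses written by [rotoscope_write_csv()]
#'
#' Supports the externally-produced-poses path: displacements can be
#' extracted from manually created poses without running the optimizer.
#' @param path CSV path.
#' @param trial_type trial type tag for the scalar extraction.
#' @return a minimal `rotoscope`-compatible object.
#' @export
rotoscope_read_csv <- function(path, trial_type = "translation_z") {
  df <- utils::read.csv(path)
  frames <- sort(unique(df$frame))
  poses <- lapply(frames, function(f) {
    lapply(c("a", "b"), function(bd) {
      r <- df[df$frame == f & df$body == bd, ]
      rigid_pose(matrix(as.numeric(r[paste0("r", rep(1:3, each = 3), rep(1:3, 3))]),
                        3, 3, byrow = TRUE),
                 as.numeric(r[c("tx", "ty", "tz")]))
    })
  })
  scores <- vapply(frames, function(f) df$score[df$frame == f][1], numeric(1))
  structure(list(trial_type = trial_type, poses = poses, scores = scores,
                 failed = rep(FALSE, length(frames)),
                 nominal = NULL,
                 axes = joint_axes(origin = poses[[1]][[2]]$translation)),
            class = "rotoscope")
}
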