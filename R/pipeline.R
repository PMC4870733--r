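# Pipeline orchestration: simulate -> calibrate -> rotoscope -> analyze,
# with a declarative JSON config, explicit seeds and on-disk artifacts.
# Ground truth is written to a separate file so the rotoscoping stage can
# run blinded, mirroring the blinded human rater.

default_run_config <- function() {
  list(seed = 1,
       grid = list(n_plates = 4),
       trial = list(type = "translation_z",
                    levels = seq(0, 20, by = 5),
                    n_per_level = NULL,
                    imaging = "t1",
                    jitter = 0.2,
                    noise_sigma = 0.03,
                    blur_fwhm = 1),
       rotoscope = list(restarts = 5, session_seeds = c(1, 2)),
       analyze = list(abs_values = TRUE))
}

#' Load and validate a pipeline run configuration
#'
#' Accepts a JSON file path or an R list; unknown keys are rejected, missing
#' keys filled from the defaults, and every random process is driven by the
#' explicit `seed`.
#' @param config JSON path or list (`NULL` for defaults).
#' @return validated config list (with a `hash` attribute of its JSON form).
#' @export
read_run_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_mrikin(sprintf("config file not found: %s", config),
                  "mrikin_config_error")
    config <- tryCatch(jsonlite::read_json(config, simplifyVector = TRUE),
                       error = function(e)
                         stop_mrikin(sprintf("config is not valid JSON: %s",
                                             conditionMessage(e)),
                                     "mrikin_config_error"))
  }
  if (is.null(config)) config <- list()
  if (!is.list(config))
    stop_mrikin("config must be a list or a JSON file path", "mrikin_config_error")
  def <- default_run_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad))
    stop_mrikin(paste("unknown config keys:", paste(bad, collapse = ", ")),
                "mrikin_config_error")
  for (sec in names(config)) {
    if (is.list(def[[sec]])) {
      badk <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(badk))
        stop_mrikin(sprintf("unknown config keys in '%s': %s", sec,
                            paste(badk, collapse = ", ")), "mrikin_config_error")
    }
  }
  cfg <- utils::modifyList(def, config)
  if (!cfg$trial$type %in% c("translation_z", "rotation_x", "biplanar"))
    stop_mrikin("trial.type must be translation_z, rotation_x or biplanar",
                "mrikin_config_error")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop_mrikin("seed must be a single integer", "mrikin_config_error")
  attr(cfg, "hash") <- substr(digest_json(cfg), 1, 12)
  cfg
}

digest_json <- function(x) {
  j <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  # tiny polynomial rolling hash; provenance tag only
  h <- 0
  for (b in utf8ToInt(as.character(j))) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

check_outdir <- function(out) {
  if (is.null(out) || !dir.exists(dirname(out)) && !dir.exists(out))
    stop_mrikin(sprintf("output directory does not exist: %s", out),
                "mrikin_config_error")
  if (!dir.exists(out)) dir.create(out)
  invisible(out)
}

#' Pipeline stages
#'
#' `cli_simulate` writes the calibration grid slices, the trial-series frame
#' images with sidecars, a trial manifest CSV and a *separate* ground-truth
#' JSON. `cli_calibrate` recovers the volume mapping from the grid images and
#' writes it as CSV + JSON with a per-plate residual report. `cli_rotoscope`
#' registers the models to every frame (blinded: the ground-truth file is
#' never read) and writes per-frame poses, scores and displacements;
#' `poses_from_file` skips the optimizer and only extracts displacements from
#' externally produced poses. `cli_analyze` runs the full reliability
#' analysis on two session CSVs. All stages return the output directory
#' invisibly and raise classed conditions (`mrikin_config_error` etc.) on
#' invalid input.
#'
#' @param config config list or JSON path (see [read_run_config()]).
#' @param out output directory (must have an existing parent).
#' @return the output directory, invisibly.
#' @export
cli_simulate <- function(config = NULL, out) {
  cfg <- read_run_config(config)
  check_outdir(out)
  grid <- grid_spec(n_plates = cfg$grid$n_plates)
  beads <- grid_bead_coordinates(grid)
  # calibration grid slices
  for (p in seq_len(grid$n_plates) - 1L) {
    spec <- grid_slice_spec(p, grid)
    pb <- beads[beads$plate == p, ]
    scene <- lapply(seq_len(nrow(pb)), function(i)
      list(solid = sphere_solid(grid$bead_diameter,
                                center = c(pb$x[i], pb$y[i], pb$z[i])),
           pose = rigid_pose()))
    img <- render_slice(scene, spec, seed = child_seed(cfg$seed, 900 + p))
    write_slice_image(img, spec, file.path(out, sprintf("grid_plate%d.tif", p)),
                      seed = cfg$seed)
  }
  # trial series
  tr <- cfg$trial
  series <- generate_trial_series(tr$type, tr$levels,
                                  n_per_level = tr$n_per_level,
                                  imaging = tr$imaging, jitter = tr$jitter,
                                  seed = cfg$seed, noise_sigma = tr$noise_sigma,
                                  blur_fwhm = tr$blur_fwhm)
  n <- length(series$frames)
  manifest <- list()
  for (i in seq_len(n)) {
    paths <- character(length(series$frames[[i]]))
    fspecs <- series$frame_specs[[i]]
    for (k in seq_along(series$frames[[i]])) {
      paths[k] <- sprintf("frame%03d_view%d.tif", i - 1L, k)
      write_slice_image(series$frames[[i]][[k]], fspecs[[k]],
                        file.path(out, paths[k]), seed = cfg$seed)
    }
    manifest[[i]] <- data.frame(frame = i - 1L, trial_type = tr$type,
                                level = series$design$level[i],
                                replicate = series$design$replicate[i],
                                view1 = paths[1],
                                view2 = if (length(paths) > 1) paths[2] else NA)
  }
  utils::write.csv(do.call(rbind, manifest), file.path(out, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(neutral = list(a = pose_to_list(series$neutral_poses$a),
                        b = pose_to_list(series$neutral_poses$b)),
         solid = series$solid[c("side", "bore_base_diameter",
                                "bore_waist_diameter", "bore_axis")],
         config_hash = attr(cfg, "hash"), seed = cfg$seed),
    file.path(out, "design.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(poses = lapply(series$ground_truth, function(g)
           list(a = pose_to_list(g$a), b = pose_to_list(g$b))),
         true_displacement = series$true_displacement,
         nominal = series$nominal),
    file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @rdname cli_simulate
#' @param indir directory holding the simulate stage outputs.
#' @export
cli_calibrate <- function(config = NULL, indir, out = indir) {
  cfg <- read_run_config(config)
  check_outdir(out)
  grid <- grid_spec(n_plates = cfg$grid$n_plates)
  images <- list()
  for (p in seq_len(grid$n_plates) - 1L) {
    f <- file.path(indir, sprintf("grid_plate%d.tif", p))
    if (!file.exists(f))
      stop_mrikin(sprintf("grid image missing: %s", f), "mrikin_config_error")
    images[[p + 1]] <- read_slice_image(f)$image
  }
  cal <- tryCatch(calibrate_volume(images, grid),
                  mrikin_error = function(e)
                    stop_mrikin(sprintf("calibration failed: %s", conditionMessage(e)),
                                "mrikin_calibration_error"))
  volume_mapping_write_csv(cal$mapping, file.path(out, "mayacam.csv"))
  volume_mapping_write_json(cal$mapping, file.path(out, "mapping.json"))
  jsonlite::write_json(
    list(per_plate_rms_px = lapply(cal$plates, function(p) p$rms_residual),
         per_plate_rms_mm = as.list(cal$mapping$per_plate_rms_mm),
         global_rms_mm = cal$mapping$rms_residual_mm,
         pixel_size_mm = cal$mapping$pixel_size_mm),
    file.path(out, "calibration_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}

read_series_from_disk <- function(indir) {
  mf <- utils::read.csv(file.path(indir, "manifest.csv"))
  design <- jsonlite::read_json(file.path(indir, "design.json"),
                                simplifyVector = TRUE)
  frames <- vector("list", nrow(mf))
  frame_specs <- vector("list", nrow(mf))
  specs <- NULL
  for (i in seq_len(nrow(mf))) {
    views <- c(mf$view1[i], if (!is.na(mf$view2[i])) mf$view2[i])
    imgs <- lapply(views, function(v) read_slice_image(file.path(indir, v)))
    frames[[i]] <- lapply(imgs, `[[`, "image")
    frame_specs[[i]] <- lapply(imgs, `[[`, "spec")
    if (is.null(specs)) specs <- frame_specs[[i]]
  }
  solid <- cube_solid(design$solid$side, design$solid$bore_base_diameter,
                      design$solid$bore_waist_diameter, design$solid$bore_axis)
  structure(list(trial_type = mf$trial_type[1],
                 design = mf[, c("frame", "level", "replicate")],
                 frames = frames, slice_specs = specs,
                 frame_specs = frame_specs,
                 nominal = mf$level,
                 neutral_poses = list(a = pose_from_list(design$neutral$a),
                                      b = pose_from_list(design$neutral$b)),
                 solid = solid, seed = design$seed),
            class = "trial_series")
}

#' @rdname cli_simulate
#' @param session which rotoscoping session (selects the optimizer seed).
#' @param poses_from_file optional CSV of externally produced poses (as from
#'   [rotoscope_write_csv()]); skips optimization.
#' @param axes_file optional joint-axes JSON saved by a previous session, so
#'   the axes assigned in session 1 are reused in session 2.
#' @export
cli_rotoscope <- function(config = NULL, indir, out = indir, session = 1L,
                          poses_from_file = NULL, axes_file = NULL) {
  cfg <- read_run_config(config)
  check_outdir(out)
  series <- read_series_from_disk(indir)
  axes <- if (!is.null(axes_file)) axes_load(axes_file) else NULL
  if (!is.null(poses_from_file)) {
    res <- rotoscope_read_csv(poses_from_file, series$trial_type)
    if (!is.null(axes)) res$axes <- axes
    res$nominal <- series$nominal
    res$displacements <- extract_displacement_series(res, axes = res$axes)
  } else {
    mf <- file.path(indir, "mapping.json")
    mapping <- if (file.exists(mf)) volume_mapping_read_json(mf) else NULL
    seeds <- cfg$rotoscope$session_seeds
    seed <- child_seed(cfg$seed, 100 + seeds[min(session, length(seeds))])
    res <- rotoscope_series(series, mapping = mapping, axes = axes,
                            seed = seed, restarts = cfg$rotoscope$restarts)
  }
  tag <- sprintf("session%d", session)
  rotoscope_write_csv(res, file.path(out, sprintf("poses_%s.csv", tag)))
  df <- res$displacements
  df$level <- series$nominal
  utils::write.csv(df, file.path(out, sprintf("displacements_%s.csv", tag)),
                   row.names = FALSE)
  axes_save(res$axes, file.path(out, sprintf("ajx_%s.json", tag)))
  invisible(out)
}

#' @rdname cli_simulate
#' @param session_csvs character(2): the two displacement CSVs to compare.
#' @export
cli_analyze <- function(config = NULL, session_csvs, out) {
  cfg <- read_run_config(config)
  check_outdir(out)
  if (length(session_csvs) != 2)
    stop_mrikin("exactly two session CSVs are required", "mrikin_config_error")
  s1 <- utils::read.csv(session_csvs[1])
  s2 <- utils::read.csv(session_csvs[2])
  if (nrow(s1) != nrow(s2))
    stop_mrikin("session trial counts do not match", "mrikin_config_error")
  unit <- if (identical(s1$trial_type[1], "rotation_x")) "deg" else "mm"
  data <- session_pair_data(s1$level, s1$measured, s2$measured)
  rep_ <- reliability_report(data, abs_values = cfg$analyze$abs_values,
                             unit = unit)
  reliability_write_csv(rep_, file.path(out, "reliability_report.csv"))
  txt <- utils::capture.output(print(rep_))
  writeLines(txt, file.path(out, "reliability_report.txt"))
  grDevices::png(file.path(out, "bland_altman.png"), width = 600, height = 600)
  plot(rep_$bland_altman)
  grDevices::dev.off()
  if ("measured_x" %in% names(s1)) {
    data_x <- session_pair_data(s1$level, s1$measured_x, s2$measured_x)
    rep_x <- reliability_report(data_x, abs_values = cfg$analyze$abs_values,
                                unit = unit)
    reliability_write_csv(rep_x, file.path(out, "reliability_report_xplane.csv"))
  }
  invisible(out)
}

#' @rdname cli_simulate
#' @export
cli_run_all <- function(config = NULL, out) {
  cfg <- read_run_config(config)
  check_outdir(out)
  cli_simulate(cfg, out)
  cli_calibrate(cfg, out)
  cli_rotoscope(cfg, out, session = 1L)
  cli_rotoscope(cfg, out, session = 2L,
                axes_file = file.path(out, "ajx_session1.json"))
  cli_analyze(cfg, file.path(out, c("displacements_session1.csv",
                                    "displacements_session2.csv")), out)
  invisible(out)
}
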