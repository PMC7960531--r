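#' Run configuration
#'
#' All settings of a desk-scale experiment in one object: scene and video
#' geometry, spectral generation, preprocessing, modelling, margins, and a
#' single seed fanned out deterministically to every stochastic step. The
#' defaults mirror the system's bench validation: a 180-frame 640x480
#' video at 0.5 mm/px, markers 20 mm apart with a 30-mm tip offset, 25
#' training spectra per class, and safety margins of 0, 1.5 and 3 mm.
#'
#' @param seed Integer master seed.
#' @param n_frames,width_px,height_px,mm_per_px Video geometry.
#' @param marker_separation_mm,tip_offset_mm,tip_diameter_mm Probe
#'   geometry.
#' @param n_train_per_class Training spectra per class.
#' @param noise_sd Spectral noise level.
#' @param margins_mm Safety margins evaluated (mm).
#' @param acquisition_stride A diagnostic acquisition is taken every this
#'   many frames along the trajectory.
#' @param threshold PLS-DA decision threshold for the positive class.
#' @param occluded_frames Frames rendered without markers.
#' @param preprocess A [preprocess_config()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_frames = 180L, width_px = 640L,
                       height_px = 480L, mm_per_px = 0.5,
                       marker_separation_mm = 20, tip_offset_mm = 30,
                       tip_diameter_mm = 2.1,
                       n_train_per_class = 25L, noise_sd = 0.3,
                       margins_mm = c(0, 1.5, 3),
                       acquisition_stride = 6L, threshold = 0.5,
                       occluded_frames = integer(0),
                       preprocess = preprocess_config()) {
  if (n_frames < 1L) stop("n_frames must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px), mm_per_px = mm_per_px,
                 marker_separation_mm = marker_separation_mm,
                 tip_offset_mm = tip_offset_mm,
                 tip_diameter_mm = tip_diameter_mm,
                 n_train_per_class = as.integer(n_train_per_class),
                 noise_sd = noise_sd, margins_mm = margins_mm,
                 acquisition_stride = as.integer(acquisition_stride),
                 threshold = threshold,
                 occluded_frames = as.integer(occluded_frames),
                 preprocess = preprocess),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$preprocess <- unclass(x$preprocess)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  pp <- if (is.null(x$preprocess)) preprocess_config() else
    do.call(preprocess_config, x$preprocess)
  x$preprocess <- NULL
  do.call(run_config, c(x, list(preprocess = pp)))
}

# scene + video implied by a run_config
config_scene <- function(config) {
  elliptical_lesion_scene(config$width_px, config$height_px,
                          mm_per_px = config$mm_per_px)
}

config_video <- function(config) {
  video_gen_spec(n_frames = config$n_frames,
                 marker_separation_mm = config$marker_separation_mm,
                 tip_offset_mm = config$tip_offset_mm,
                 occluded_frames = config$occluded_frames,
                 seed = config$seed)
}

#' Simulate a complete synthetic experiment to disk
#'
#' Writes everything a real session would have produced: the PNG frame
#' sequence, the exact ground-truth tracking table, the ground-truth
#' lesion mask, labelled training spectra as CSVs, and the run
#' configuration — all deterministic functions of the config and its seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of the paths written.
#' @export
cmd_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scene <- config_scene(config)
  video <- config_video(config)
  vid <- generate_probe_video(scene, video, dir = file.path(out_dir, "frames"))
  utils::write.csv(vid$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  png::writePNG(scene$lesion_mask * 1, file.path(out_dir, "truth_mask.png"))
  specs <- default_class_specs(noise_sd = config$noise_sd)
  train <- generate_spectra_set(specs, config$n_train_per_class,
                                seed = config$seed)
  spectra_dir <- file.path(out_dir, "spectra")
  for (i in seq_along(train$spectra)) {
    cls_dir <- file.path(spectra_dir, train$labels[i])
    dir.create(cls_dir, showWarnings = FALSE, recursive = TRUE)
    write_spectrum_csv(train$spectra[[i]],
                       file.path(cls_dir, sprintf("spectrum_%03d.csv", i)))
  }
  write_run_config(config, file.path(out_dir, "config.yaml"))
  # HSV calibration from the first clean frame, seeded at the true centers
  calib_frame <- setdiff(seq_len(config$n_frames), config$occluded_frames)[1]
  if (!is.na(calib_frame)) {
    tr <- vid$truth[calib_frame, ]
    specs <- calibrate_hsv(png::readPNG(vid$frames[calib_frame]),
                           list(proximal = c(tr$mx1, tr$my1),
                                distal = c(tr$mx2, tr$my2)))
    yaml::write_yaml(
      list(markers = lapply(specs, function(s) lapply(unclass(s), as.vector)),
           geometry = list(marker_separation_mm = config$marker_separation_mm,
                           tip_offset_mm = config$tip_offset_mm,
                           tip_diameter_mm = config$tip_diameter_mm)),
      file.path(out_dir, "calibration.yaml"))
  }
  invisible(list(frames = vid$frames,
                 truth = file.path(out_dir, "truth.csv"),
                 truth_mask = file.path(out_dir, "truth_mask.png"),
                 spectra = spectra_dir,
                 config = file.path(out_dir, "config.yaml")))
}

#' Run the full margin-delineation workflow
#'
#' The end-to-end pipeline on a synthetic experiment: render the probe
#' video, calibrate marker HSV windows from the first clean frame, track
#' every frame independently, train the PLS-DA model on labelled spectra,
#' then walk the trajectory taking a spectral acquisition every
#' `acquisition_stride` frames — each one classified and recorded at the
#' tracked tip — and finally delineate the lesion at every configured
#' safety margin and score it against the ground-truth mask.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory for artifacts (overlay PNG, store and
#'   metrics CSVs, JSON summary, run.log); nothing is written when `NULL`.
#' @param oracle_classifier Use the ground-truth lesion mask instead of
#'   the PLS-DA prediction for each acquisition (isolates geometric
#'   delineation accuracy from spectral model accuracy).
#' @return List with `tracking` (pose table), `tracking_stats`, `model`,
#'   `cv`, `store`, `delineations` (one `delineation_result` per margin),
#'   `metrics` (margin sweep data frame), `truth_mask`, `config`.
#' @export
run_experiment <- function(config, out_dir = NULL, oracle_classifier = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  scene <- config_scene(config)
  video <- config_video(config)
  trajectory <- default_trajectory(config$n_frames, scene)
  video$trajectory <- trajectory
  say("seed %d: rendering %d frames (%dx%d, %.2f mm/px)",
      config$seed, config$n_frames, config$width_px, config$height_px,
      config$mm_per_px)
  vid <- generate_probe_video(scene, video)

  # calibrate on the first non-occluded frame, seeded at true marker centers
  calib_frame <- setdiff(seq_len(config$n_frames), config$occluded_frames)[1]
  tr <- vid$truth[calib_frame, ]
  fr1 <- vid$frames[[calib_frame]]
  specs <- calibrate_hsv(fr1, list(proximal = c(tr$mx1, tr$my1),
                                   distal = c(tr$mx2, tr$my2)))
  geom <- probe_geometry(config$marker_separation_mm, config$tip_offset_mm,
                         config$tip_diameter_mm)
  poses <- track_video(vid$frames, specs, geom)
  stats <- tracking_error(poses, vid$truth, scene$mm_per_px)
  say("tracking: mean error %.3f mm over %d valid frames",
      stats$mean_mm, stats$n_valid_frames)

  class_specs <- default_class_specs(noise_sd = config$noise_sd)
  train <- generate_spectra_set(class_specs, config$n_train_per_class,
                                seed = config$seed)
  dataset <- preprocess_set(train$spectra, train$labels, config$preprocess)
  model <- fit_plsda(dataset, n_components = 2L,
                     positive_class = "phantom",
                     threshold = config$threshold)
  cv <- venetian_blinds_cv(dataset, n_components = 2L, n_splits = 10L)
  say("PLS-DA: %d LVs, venetian-blinds CV accuracy %.1f%% (%d splits)",
      model$n_components, 100 * cv$overall_accuracy, cv$n_splits)

  store <- diagnosis_store()
  acq_frames <- seq(1L, config$n_frames, by = config$acquisition_stride)
  acq_id <- 0L
  for (f in acq_frames) {
    row <- poses[f, ]
    if (!row$valid) next
    acq_id <- acq_id + 1L
    tipx <- round(row$tipx); tipy <- round(row$tipy)
    in_lesion <- tipx >= 1 && tipx <= scene$width_px &&
      tipy >= 1 && tipy <= scene$height_px &&
      scene$lesion_mask[tipy, tipx]
    true_class <- if (in_lesion) "phantom" else "muscle"
    spec <- class_specs[[true_class]]
    s <- generate_spectrum(spec, seed = config$seed + 50000L + 17L * f)
    diag <- if (oracle_classifier) {
      structure(list(label = true_class,
                     scores = stats::setNames(as.numeric(in_lesion), true_class),
                     positive = in_lesion), class = "diagnosis")
    } else {
      predict(model, preprocess(s, config$preprocess))
    }
    pose <- structure(list(tip_px = c(row$tipx, row$tipy),
                           mm_per_px = row$mm_per_px, valid = TRUE),
                      class = "probe_pose")
    store <- add_diagnosis(store, pose, diag)
    say("acquisition %d @ frame %d (%.0f, %.0f): %s%s",
        nrow(store$records), f, row$tipx, row$tipy, diag$label,
        if (diag$positive) " [positive]" else "")
  }

  rec <- store$records
  positives <- rec[rec$positive, c("tipx", "tipy"), drop = FALSE]
  scale_est <- stats::median(rec$mm_per_px)
  metrics <- margin_sweep_report(positives, scene$lesion_mask,
                                 config$margins_mm, scale_est,
                                 tip_diameter_mm = config$tip_diameter_mm)
  delineations <- lapply(config$margins_mm, function(m) {
    build_boundary(positives, m, scale_est, dim(scene$lesion_mask),
                   tip_diameter_mm = config$tip_diameter_mm)
  })
  names(delineations) <- paste0("margin_", config$margins_mm)
  say("delineation: %d positives, tp at margins [%s] = [%s]%%",
      nrow(positives), paste(config$margins_mm, collapse = ", "),
      paste(sprintf("%.1f", metrics$tp_pct), collapse = ", "))

  result <- list(tracking = poses, tracking_stats = stats, model = model,
                 cv = cv, store = store, delineations = delineations,
                 metrics = metrics, truth_mask = scene$lesion_mask,
                 config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(poses, file.path(out_dir, "poses.csv"), row.names = FALSE)
    write_store_csv(store, file.path(out_dir, "diagnoses.csv"))
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    overlay <- render_overlay(vid$frames[[config$n_frames]], store,
                              delineations[[length(delineations)]])
    png::writePNG(overlay, file.path(out_dir, "overlay.png"))
    summary <- list(seed = config$seed,
                    tracking_mean_mm = stats$mean_mm,
                    tracking_sd_mm = stats$sd_mm,
                    cv_accuracy = cv$overall_accuracy,
                    n_acquisitions = nrow(rec),
                    n_positive = sum(rec$positive),
                    metrics = metrics,
                    config = unclass(config)[setdiff(names(unclass(config)),
                                                     "preprocess")])
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  result
}
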