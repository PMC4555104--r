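# The stage-chaining pipeline: simulate (optional) -> detect -> localize
# -> drift -> merge -> filter -> clusters -> render, with per-stage
# tables, a run log, and record-count invariants.

#' Pipeline configuration
#'
#' Collects the per-stage parameter objects plus run-level settings into
#' one validated list. Any component left NULL gets its module default.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Output directory for tables and the run log; NULL
#'   keeps everything in memory.
#' @param n_frames Movie length, frames.
#' @param field_px Frame size in pixels (width, height).
#' @param layout A \code{phantom_layout} (for simulated input).
#' @param kinetics,camera,detection,merge,filter,render Stage parameter
#'   objects.
#' @param drift_injected Optional true drift trajectory to apply while
#'   rendering (data.frame \code{frame, dx_nm, dy_nm}).
#' @param drift_correct Enable drift estimation/correction.
#' @param drift_batch_size,drift_bin_nm,drift_degree Drift-estimation
#'   settings.
#' @param roi_grid_nm,roi_min_count ROI proposal settings.
#' @param resolution_nm Cluster-thickness discard threshold; NULL uses
#'   the dataset's mean localization precision.
#' @return An object of class \code{palm_config}.
#' @export
palm_config <- function(seed = 1, out_dir = NULL, n_frames = 4000,
                        field_px = c(64, 64), layout = NULL,
                        kinetics = kinetics_params(),
                        camera = camera_params(),
                        detection = detection_params(),
                        merge = NULL, filter = filter_params(),
                        render = render_params(),
                        drift_injected = NULL, drift_correct = TRUE,
                        drift_batch_size = 1000, drift_bin_nm = 100,
                        drift_degree = 3,
                        roi_grid_nm = 100, roi_min_count = 5,
                        resolution_nm = 25) {
  if (is.null(merge))
    merge <- merge_params(capture_radius_nm = camera$pixel_size_nm,
                          frame_interval_s = camera$frame_interval_s)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_frames = as.integer(n_frames), field_px = field_px,
                 layout = layout, kinetics = kinetics, camera = camera,
                 detection = detection, merge = merge, filter = filter,
                 render = render, drift_injected = drift_injected,
                 drift_correct = isTRUE(drift_correct),
                 drift_batch_size = drift_batch_size,
                 drift_bin_nm = drift_bin_nm, drift_degree = drift_degree,
                 roi_grid_nm = roi_grid_nm, roi_min_count = roi_min_count,
                 resolution_nm = resolution_nm),
            class = "palm_config")
}

log_stage <- function(log, stage, n_in, n_out, note = "") {
  rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                        note = note))
}

#' Run the full analysis chain
#'
#' Either simulates a movie from \code{config$layout} or analyses a
#' supplied \code{frame_stack} / localization table. Every stage's
#' output is kept in the returned bundle (and written to
#' \code{config$out_dir} when set), together with a run log holding the
#' record counts in and out of each stage. Count invariants (filters
#' never grow a table; mergers conserve total detections) are asserted.
#'
#' @param config A \code{palm_config}.
#' @param stack Optional input movie (skips simulation).
#' @param locs Optional input localization table (skips detection and
#'   localization).
#' @return list with elements \code{emitters} (simulated runs only),
#'   \code{stack}, \code{detections}, \code{locs}, \code{drift},
#'   \code{molecules_raw}, \code{molecules}, \code{filtered},
#'   \code{rois}, \code{cluster_fits}, \code{summary}, \code{image},
#'   \code{log}.
#' @export
run_pipeline <- function(config, stack = NULL, locs = NULL) {
  stopifnot(inherits(config, "palm_config"))
  log <- data.frame(stage = character(0), n_in = integer(0),
                    n_out = integer(0), note = character(0))
  out <- list()
  # -- simulate ------------------------------------------------------------
  if (is.null(stack) && is.null(locs)) {
    if (is.null(config$layout)) stop("[simulate] no layout and no input data")
    emitters <- build_phantom(config$layout, seed = config$seed)
    emitters <- simulate_kinetics(emitters, config$kinetics, config$n_frames,
                                  config$camera$frame_interval_s,
                                  seed = config$seed)
    stack <- render_movie(emitters, config$camera, config$n_frames,
                          config$field_px, drift = config$drift_injected,
                          seed = config$seed)
    out$emitters <- emitters
    log <- log_stage(log, "simulate", nrow(emitters), length(stack$frames),
                     "emitters in, frames out")
  }
  out$stack <- stack
  # -- detect + localize ---------------------------------------------------
  if (is.null(locs)) {
    detections <- detect_movie(stack, config$detection)
    log <- log_stage(log, "detect", length(stack$frames), nrow(detections),
                     "frames in, candidates out")
    locs <- localize(stack, detections, config$detection)
    n_ok <- sum(locs$fit_ok)
    log <- log_stage(log, "localize", nrow(detections), n_ok,
                     sprintf("%d fits failed", nrow(locs) - n_ok))
    stopifnot(nrow(locs) <= max(nrow(detections), 1))
    out$detections <- detections
  }
  out$locs <- locs
  locs_ok <- locs[if (!is.null(locs$fit_ok)) locs$fit_ok else TRUE, ]
  # -- drift ---------------------------------------------------------------
  if (config$drift_correct &&
      nrow(locs_ok) >= 2 * config$drift_batch_size) {
    traj <- estimate_drift(locs_ok, n_frames = config$n_frames,
                           batch_size = config$drift_batch_size,
                           bin_size_nm = config$drift_bin_nm,
                           degree = config$drift_degree)
    locs_ok <- correct_drift(locs_ok, traj)
    out$drift <- traj
    log <- log_stage(log, "drift", nrow(locs_ok), nrow(locs_ok),
                     sprintf("max |dx|=%.0f nm, max |dy|=%.0f nm",
                             max(abs(traj$dx_nm)), max(abs(traj$dy_nm))))
  } else if (config$drift_correct) {
    log <- log_stage(log, "drift", nrow(locs_ok), nrow(locs_ok),
                     "skipped: fewer than 2 full batches")
  }
  # -- merge ---------------------------------------------------------------
  mols_raw <- link_consecutive(locs_ok, config$merge)
  stopifnot(sum(mols_raw$n_detections) == nrow(locs_ok))
  mols <- link_blinking(mols_raw, config$merge)
  stopifnot(sum(mols$n_detections) == nrow(locs_ok))
  log <- log_stage(log, "merge_consecutive", nrow(locs_ok), nrow(mols_raw))
  log <- log_stage(log, "merge_blinking", nrow(mols_raw), nrow(mols))
  out$molecules_raw <- mols_raw
  out$molecules <- mols
  # -- density filter ------------------------------------------------------
  filt <- filter_outliers(mols, config$filter)
  stopifnot(nrow(filt$retained) <= nrow(mols))
  log <- log_stage(log, "density_filter", nrow(mols), nrow(filt$retained))
  out$filtered <- filt$retained
  # -- clusters ------------------------------------------------------------
  res_nm <- config$resolution_nm
  if (is.null(res_nm) && nrow(locs_ok) > 0 &&
      !is.null(locs_ok$precision_nm))
    res_nm <- mean_resolution(locs_ok)$mean_nm
  if (nrow(filt$retained) > 0) {
    rois <- propose_rois(filt$retained, grid_nm = config$roi_grid_nm,
                         min_count = config$roi_min_count)
    fits <- analyze_clusters(filt$retained, rois,
                             resolution_nm = res_nm %||% 25)
    out$rois <- rois
    out$cluster_fits <- fits
    if (nrow(fits) > 0 && any(fits$retained))
      out$summary <- summarize_clusters(fits)
    log <- log_stage(log, "clusters", nrow(filt$retained),
                     if (is.null(out$cluster_fits)) 0L else nrow(fits))
  } else {
    out$rois <- list()
    out$cluster_fits <- NULL
    log <- log_stage(log, "clusters", 0L, 0L, "no molecules survived")
  }
  # -- render --------------------------------------------------------------
  if (nrow(filt$retained) > 0)
    out$image <- render_palm(filt$retained, config$render)
  out$log <- log
  if (!is.null(config$out_dir)) write_bundle(out, config)
  out
}

write_bundle <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  if (!is.null(out$emitters)) write_ground_truth(out$emitters,
                                                 p("ground_truth.csv"))
  if (!is.null(out$detections)) write_table_csv(out$detections,
                                                p("detections.csv"))
  if (!is.null(out$locs)) write_table_csv(out$locs, p("localizations.csv"))
  if (!is.null(out$drift)) write_drift(out$drift, p("drift.csv"))
  if (!is.null(out$molecules)) write_table_csv(out$molecules,
                                               p("molecules.csv"))
  if (!is.null(out$filtered)) write_table_csv(out$filtered,
                                              p("molecules_filtered.csv"))
  if (!is.null(out$rois) && length(out$rois) > 0)
    write_rois(out$rois, p("rois.json"))
  if (!is.null(out$cluster_fits)) write_table_csv(out$cluster_fits,
                                                  p("clusters.csv"))
  write_table_csv(out$log, p("run_log.csv"))
  cfgpath <- p("config.json")
  cfg <- config
  cfg$layout <- NULL; cfg$drift_injected <- NULL
  jsonlite::write_json(lapply(unclass(cfg), function(x)
    if (is.atomic(x) || is.null(x)) x else unclass(x)),
    cfgpath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}
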