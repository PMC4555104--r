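# PALM image rendering and plain-text file I/O for all pipeline tables.

#' Rendering parameters
#'
#' "Width" always means the FWHM of the rendered spot. In
#' \code{per_point} mode each localization is drawn at its own precision
#' instead of a fixed width.
#'
#' @param mode \code{"gaussian"} (unit-integral Gaussian per point) or
#'   \code{"histogram"} (plain 2D binning).
#' @param spot_width_nm FWHM of the rendered spot, nm (e.g. 214 nm = two
#'   107 nm camera pixels for a diffraction-limited look).
#' @param output_pixel_nm Pitch of the rendering grid, nm.
#' @param per_point Use each point's \code{precision_nm} as its width.
#' @return An object of class \code{render_params}.
#' @export
render_params <- function(mode = c("gaussian", "histogram"),
                          spot_width_nm = 214, output_pixel_nm = 20,
                          per_point = FALSE) {
  mode <- match.arg(mode)
  stopifnot(spot_width_nm > 0, output_pixel_nm > 0)
  structure(list(mode = mode, spot_width_nm = spot_width_nm,
                 output_pixel_nm = output_pixel_nm,
                 per_point = isTRUE(per_point)),
            class = "render_params")
}

#' Render localizations into a super-resolution (or pseudo wide-field) image
#'
#' In Gaussian mode each point adds a pixel-integrated Gaussian of unit
#' integral, so the image total equals the number of points (up to
#' boundary clipping). In histogram mode each point adds one count to
#' its bin.
#'
#' @param points data.frame with \code{x_nm, y_nm} (and
#'   \code{precision_nm} for per-point widths).
#' @param params A \code{render_params}.
#' @param extent list(xlim, ylim) in nm; default is the point range
#'   padded by two spot widths.
#' @return Numeric matrix (rows = y) with attributes \code{extent} and
#'   \code{pixel_nm}.
#' @export
render_palm <- function(points, params = render_params(), extent = NULL) {
  stopifnot(inherits(params, "render_params"))
  if (nrow(points) == 0) stop("no points to render")
  pad <- 3 * params$spot_width_nm
  if (is.null(extent))
    extent <- list(xlim = range(points$x_nm) + c(-pad, pad),
                   ylim = range(points$y_nm) + c(-pad, pad))
  p <- params$output_pixel_nm
  nx <- max(1L, as.integer(ceiling((extent$xlim[2] - extent$xlim[1]) / p)))
  ny <- max(1L, as.integer(ceiling((extent$ylim[2] - extent$ylim[1]) / p)))
  if (nx < 1 || ny < 1) stop("zero-size rendering grid")
  img <- matrix(0, ny, nx)
  if (params$mode == "histogram") {
    bx <- floor((points$x_nm - extent$xlim[1]) / p)
    by <- floor((points$y_nm - extent$ylim[1]) / p)
    ok <- bx >= 0 & bx < nx & by >= 0 & by < ny
    for (i in which(ok)) img[by[i] + 1L, bx[i] + 1L] <-
        img[by[i] + 1L, bx[i] + 1L] + 1
  } else {
    widths <- if (params$per_point && !is.null(points$precision_nm))
      points$precision_nm else rep(params$spot_width_nm, nrow(points))
    n_clip <- 0L
    for (i in seq_len(nrow(points))) {
      sig_px <- fwhm_to_sigma(widths[i]) / p
      x_px <- (points$x_nm[i] - extent$xlim[1]) / p - 0.5
      y_px <- (points$y_nm[i] - extent$ylim[1]) / p - 0.5
      pw <- psf_pixel_weights(x_px, y_px, sig_px, ceiling(6 * sig_px), nx, ny)
      if (is.null(pw)) { n_clip <- n_clip + 1L; next }
      img[pw$iy + 1L, pw$ix + 1L] <- img[pw$iy + 1L, pw$ix + 1L] + pw$w
    }
    if (n_clip > 0L) message(n_clip, " points fell outside the rendered field")
  }
  attr(img, "extent") <- extent
  attr(img, "pixel_nm") <- p
  img
}

#' Measure the FWHM of an isolated rendered spot
#'
#' Takes the profile through the brightest pixel along one axis and
#' returns the linearly interpolated full width at half maximum in nm.
#'
#' @param img Matrix from \code{\link{render_palm}}.
#' @param axis "x" or "y".
#' @return FWHM in nm.
#' @export
measure_fwhm <- function(img, axis = c("x", "y")) {
  axis <- match.arg(axis)
  p <- attr(img, "pixel_nm")
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  prof <- if (axis == "x") img[pk[1], ] else img[, pk[2]]
  half <- max(prof) / 2
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  # linear interpolation of the half-maximum crossings
  left <- if (lo > 1)
    lo - (prof[lo] - half) / (prof[lo] - prof[lo - 1]) else lo
  right <- if (hi < length(prof))
    hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1]) else hi
  (right - left) * p
}

# ---- table / stack / ROI I/O (plain text) ---------------------------------

#' Write and read pipeline tables (CSV)
#'
#' All pipeline tables (detections, localizations, molecules, cluster
#' fits) are written as plain CSV with a header; floats are written at
#' full precision (\code{digits = 17}) so write-then-read round-trips
#' exactly.
#'
#' @param df A data.frame (list columns are dropped with a message).
#' @param path File path.
#' @return \code{read_table_csv} returns the data.frame.
#' @export
write_table_csv <- function(df, path) {
  is_list <- vapply(df, is.list, logical(1))
  if (any(is_list)) {
    message("dropping list column(s): ",
            paste(names(df)[is_list], collapse = ", "))
    df <- df[!is_list]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col))
        format(col, digits = 17, scientific = TRUE, trim = TRUE)
      else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Import a ThunderSTORM-style localization table
#'
#' Maps the common ThunderSTORM export column names (\code{"x [nm]"},
#' \code{"y [nm]"}, \code{"frame"}, \code{"uncertainty [nm]"}, ...) onto
#' this package's localization columns.
#'
#' @param path CSV file path.
#' @return Localization data.frame with \code{frame, x_nm, y_nm,
#'   precision_nm, photons, fit_ok}.
#' @export
read_thunderstorm <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
    rep(NA_real_, nrow(df))
  }
  out <- data.frame(
    frame = as.integer(pick("frame")),
    x_nm = pick("x [nm]", "x_nm", "x"),
    y_nm = pick("y [nm]", "y_nm", "y"),
    precision_nm = pick("uncertainty [nm]", "uncertainty_xy [nm]",
                        "precision_nm"),
    photons = pick("intensity [photon]", "photons"))
  out$fit_ok <- TRUE
  out$id <- seq_len(nrow(out)) - 1L
  out
}

#' Write and read frame stacks as plain text
#'
#' Portable text serialisation of a movie: a JSON header line with the
#' geometry and camera parameters, then one whitespace-separated line of
#' rounded integer counts per frame (row-major). Intended for small test
#' movies; real acquisitions would come in as TIFF stacks through a
#' format converter.
#'
#' @param stack A \code{frame_stack}.
#' @param path File path.
#' @return \code{read_stack_text} returns the \code{frame_stack}.
#' @export
write_stack_text <- function(stack, path) {
  d <- dim(stack$frames[[1]])
  hdr <- jsonlite::toJSON(c(list(ny = d[1], nx = d[2],
                                 n_frames = length(stack$frames)),
                            unclass(stack$camera)), auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  for (f in stack$frames)
    writeLines(paste(as.integer(round(t(f))), collapse = " "), con)
  invisible(path)
}

#' @rdname write_stack_text
#' @export
read_stack_text <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  cam <- camera_params(pixel_size_nm = hdr$pixel_size_nm,
                       psf_sigma_px = hdr$psf_sigma_px,
                       frame_interval_s = hdr$frame_interval_s,
                       em_gain = hdr$em_gain, read_noise = hdr$read_noise,
                       baseline = hdr$baseline,
                       background_photons = hdr$background_photons)
  frames <- lapply(lines[-1], function(l) {
    v <- as.numeric(strsplit(trimws(l), " +")[[1]])
    matrix(v, hdr$ny, hdr$nx, byrow = TRUE)
  })
  structure(list(frames = frames, camera = cam), class = "frame_stack")
}

#' Write and read ROI polygon lists (JSON)
#'
#' @param rois List of \code{roi_polygon}.
#' @param path File path.
#' @return \code{read_rois} returns the list of \code{roi_polygon}.
#' @export
write_rois <- function(rois, path) {
  payload <- lapply(rois, function(r)
    list(label = r$label, x = r$vertices[, 1], y = r$vertices[, 2]))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(payload, function(r)
    roi_polygon(cbind(unlist(r$x), unlist(r$y)), label = r$label))
}

#' Write a drift trajectory table
#'
#' @param traj A \code{drift_trajectory}.
#' @param path File path.
#' @export
write_drift <- function(traj, path) {
  write_table_csv(as.data.frame(traj), path)
}
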