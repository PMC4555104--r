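# Sub-pixel localization by least-squares 2D Gaussian fitting, with
# per-localization precision and signal-to-noise estimates.

#' Thompson-style localization precision (per axis)
#'
#' \deqn{\Delta x^2 = \frac{s^2 + a^2/12}{N} + \frac{8 \pi s^4 b^2}{a^2 N^2}}
#' where \eqn{s} is the PSF standard deviation in nm, \eqn{a} the pixel
#' size in nm, \eqn{N} the collected photon count and \eqn{b} the
#' background noise standard deviation in photons.
#'
#' @param s_nm PSF sigma, nm.
#' @param a_nm Pixel size, nm.
#' @param N Photons in the spot.
#' @param b Background noise sd, photons per pixel.
#' @return Per-axis localization precision, nm.
#' @export
thompson_precision <- function(s_nm, a_nm, N, b) {
  if (any(N <= 0)) stop("photon count must be positive")
  sqrt((s_nm^2 + a_nm^2 / 12) / N + 8 * pi * s_nm^4 * b^2 / (a_nm^2 * N^2))
}

#' Per-localization precision from a fitted spot
#'
#' Evaluates \code{\link{thompson_precision}} with the camera's PSF width
#' and pixel size and the localization's estimated photon count and
#' background noise.
#'
#' @param loc One row of a localization table (needs \code{photons} and
#'   \code{bg_noise_photons}).
#' @param camera A \code{camera_params}.
#' @return Per-axis precision in nm.
#' @export
estimate_precision <- function(loc, camera) {
  thompson_precision(camera$psf_sigma_px * camera$pixel_size_nm,
                     camera$pixel_size_nm, loc$photons, loc$bg_noise_photons)
}

# objective + gradient for the symmetric Gaussian spot model
# I(x,y) = A exp(-((x-x0)^2+(y-y0)^2)/(2 s^2)) + b, pixel-centre sampled
spot_model <- function(par, gx, gy, s) {
  ex <- exp(-((gx - par[1])^2) / (2 * s^2))
  ey <- exp(-((gy - par[2])^2) / (2 * s^2))
  list(ex = ex, ey = ey, m = par[3] * outer(ey, ex) + par[4])
}

#' Fit a symmetric 2D Gaussian to one detected spot
#'
#' Least-squares fit of \code{A * exp(-((x-x0)^2 + (y-y0)^2)/(2 s^2)) + b}
#' over a square window centred on the detection, with \code{s} fixed to
#' the configured PSF sigma (set \code{free_sigma = TRUE} for a
#' diagnostic free-width fit). Coordinates are returned in nm.
#'
#' @param frame Numeric matrix of camera counts.
#' @param detection One row of a detection table (\code{px, py} 0-based
#'   pixel coordinates).
#' @param params A \code{detection_params}.
#' @param camera A \code{camera_params}.
#' @param free_sigma Fit the PSF width as well.
#' @return One-row data.frame: \code{frame, x_nm, y_nm, amplitude,
#'   background, photons, bg_noise_photons, precision_nm, snr, fit_ok,
#'   residual_norm, sigma_px}. \code{precision_nm} is the radial (2D)
#'   uncertainty \eqn{\sqrt{\Delta x^2 + \Delta y^2}}; the per-axis value
#'   is \code{precision_nm / sqrt(2)}.
#' @export
fit_spot <- function(frame, detection, params, camera, free_sigma = FALSE) {
  h <- params$window_half_size
  s <- params$psf_sigma_px
  cx <- as.integer(round(detection$px))
  cy <- as.integer(round(detection$py))
  bad <- function(reason) {
    data.frame(frame = detection$frame, x_nm = NA_real_, y_nm = NA_real_,
               amplitude = NA_real_, background = NA_real_,
               photons = NA_real_, bg_noise_photons = NA_real_,
               precision_nm = NA_real_, snr = NA_real_, fit_ok = FALSE,
               residual_norm = NA_real_, sigma_px = NA_real_,
               reason = reason)
  }
  nx <- ncol(frame); ny <- nrow(frame)
  if (cx - h < 0 || cx + h > nx - 1 || cy - h < 0 || cy + h > ny - 1)
    return(bad("window clipped at frame edge"))
  gx <- (cx - h):(cx + h)            # pixel-centre x coordinates, px
  gy <- (cy - h):(cy + h)
  win <- frame[gy + 1L, gx + 1L]
  b0 <- stats::median(win)
  a0 <- max(win) - b0
  if (a0 <= 0) return(bad("flat window"))
  # centroid of background-subtracted counts for the position start
  wpos <- pmax(win - b0, 0)
  x0 <- sum(outer(rep(1, length(gy)), gx) * wpos) / sum(wpos)
  y0 <- sum(outer(gy, rep(1, length(gx))) * wpos) / sum(wpos)
  obj <- function(par) {
    sl <- if (free_sigma) par[5] else s
    if (sl <= 0.2) return(1e12)
    sum((spot_model(par, gx, gy, sl)$m - win)^2)
  }
  grad <- function(par) {
    sl <- if (free_sigma) max(par[5], 0.2) else s
    sm <- spot_model(par, gx, gy, sl)
    r2 <- 2 * (sm$m - win)
    E <- outer(sm$ey, sm$ex)
    dA <- sum(r2 * E)
    dB <- sum(r2)
    dx0 <- sum(r2 * par[3] * E * outer(rep(1, length(gy)), gx - par[1])) / sl^2
    dy0 <- sum(r2 * par[3] * E * outer(gy - par[2], rep(1, length(gx)))) / sl^2
    g <- c(dx0, dy0, dA, dB)
    if (free_sigma) {
      d2 <- outer((gy - par[2])^2, rep(1, length(gx))) +
            outer(rep(1, length(gy)), (gx - par[1])^2)
      g <- c(g, sum(r2 * par[3] * E * d2) / sl^3)
    }
    g
  }
  par0 <- c(x0, y0, a0, b0)
  if (free_sigma) par0 <- c(par0, s)
  fit <- tryCatch(
    stats::optim(par0, obj, grad, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad("optimizer failure"))
  par <- fit$par
  s_fit <- if (free_sigma) par[5] else s
  # reject runaway fits: centre must stay inside the window
  if (par[3] <= 1e-6 * max(1, abs(par[4])) ||
      par[1] < min(gx) - 1 || par[1] > max(gx) + 1 ||
      par[2] < min(gy) - 1 || par[2] > max(gy) + 1)
    return(bad("degenerate fit"))
  resid <- spot_model(par, gx, gy, s_fit)$m - win
  noise_sd <- stats::mad(as.vector(resid))
  if (noise_sd <= 0) noise_sd <- stats::sd(as.vector(resid))
  photons <- max((par[3] / camera$em_gain) * 2 * pi * s_fit^2, 1e-9)
  bg_noise <- max(noise_sd / camera$em_gain, 0)
  prec_axis <- thompson_precision(s_fit * camera$pixel_size_nm,
                                  camera$pixel_size_nm, photons, bg_noise)
  data.frame(frame = detection$frame,
             x_nm = par[1] * camera$pixel_size_nm,
             y_nm = par[2] * camera$pixel_size_nm,
             amplitude = par[3], background = par[4],
             photons = photons, bg_noise_photons = bg_noise,
             precision_nm = sqrt(2) * prec_axis,
             snr = par[3] / noise_sd, fit_ok = TRUE,
             residual_norm = sqrt(sum(resid^2)) / length(win),
             sigma_px = s_fit, reason = "")
}

#' Localize every detected candidate of a movie
#'
#' @param stack A \code{frame_stack}.
#' @param detections Candidate table from \code{\link{detect_movie}}.
#' @param params A \code{detection_params}.
#' @param free_sigma Passed to \code{\link{fit_spot}}.
#' @return Localization table (one row per candidate, including failed
#'   fits with \code{fit_ok = FALSE}).
#' @export
localize <- function(stack, detections, params = detection_params(),
                     free_sigma = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  if (nrow(detections) == 0)
    return(fit_spot(matrix(0, 3, 3), data.frame(frame = 0, px = 1, py = 1),
                    detection_params(psf_sigma_px = 0.4, window_half_size = 2),
                    stack$camera)[0, ])
  out <- vector("list", nrow(detections))
  for (i in seq_len(nrow(detections))) {
    d <- detections[i, ]
    out[[i]] <- fit_spot(stack$frames[[d$frame + 1L]], d, params,
                         stack$camera, free_sigma = free_sigma)
  }
  res <- do.call(rbind, out)
  res$id <- seq_len(nrow(res)) - 1L
  res
}

#' Mean localization precision ("resolution") of a dataset
#'
#' @param locs Localization table.
#' @param use_failed Include rows with \code{fit_ok = FALSE} (never
#'   useful; for symmetry only).
#' @return list with \code{mean_nm}, \code{sd_nm} and \code{n}.
#' @export
mean_resolution <- function(locs, use_failed = FALSE) {
  keep <- if (use_failed) rep(TRUE, nrow(locs)) else locs$fit_ok
  p <- locs$precision_nm[keep & is.finite(locs$precision_nm)]
  if (length(p) == 0) stop("no successful localizations")
  list(mean_nm = mean(p), sd_nm = stats::sd(p), n = length(p))
}
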