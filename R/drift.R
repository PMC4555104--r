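# Fiducial-free drift correction: batched 2D localization histograms,
# phase correlation between consecutive batches with sub-pixel Gaussian
# peak interpolation, polynomial interpolation over frames, subtraction.

#' Split a localization table into consecutive batches
#'
#' Localizations are ordered by frame and partitioned into
#' non-overlapping subsets of \code{batch_size} (the last one may be
#' smaller). Every localization lands in exactly one subset.
#'
#' @param locs Localization table (needs \code{frame}).
#' @param batch_size Localizations per batch (default 1000).
#' @return List of data.frames in temporal order.
#' @export
batch_localizations <- function(locs, batch_size = 1000) {
  stopifnot(batch_size >= 100)
  if (nrow(locs) < 2 * batch_size)
    stop("drift correction refused: fewer than 2 full batches of ",
         batch_size, " localizations")
  ord <- order(locs$frame)
  locs <- locs[ord, ]
  grp <- (seq_len(nrow(locs)) - 1L) %/% batch_size
  unname(split(locs, grp))
}

#' 2D histogram image of a localization subset
#'
#' Bins are half-open (\code{[edge, edge + bin)}), so a point exactly on
#' an edge goes to the higher bin. All subsets of one movie must use the
#' same \code{extent} so their images are registered on a common grid.
#'
#' @param subset Localization data.frame (\code{x_nm, y_nm}).
#' @param bin_size_nm Bin pitch, nm.
#' @param extent list(xlim, ylim) in nm; defaults to the subset's range.
#' @return Integer count matrix (rows = y bins, cols = x bins); points
#'   outside the extent are dropped.
#' @export
histogram_image <- function(subset, bin_size_nm, extent = NULL) {
  stopifnot(bin_size_nm > 0)
  if (nrow(subset) == 0) stop("empty subset")
  if (is.null(extent))
    extent <- list(xlim = range(subset$x_nm), ylim = range(subset$y_nm))
  nx <- max(1L, as.integer(ceiling((extent$xlim[2] - extent$xlim[1]) /
                                     bin_size_nm)) + 1L)
  ny <- max(1L, as.integer(ceiling((extent$ylim[2] - extent$ylim[1]) /
                                     bin_size_nm)) + 1L)
  bx <- floor((subset$x_nm - extent$xlim[1]) / bin_size_nm)
  by <- floor((subset$y_nm - extent$ylim[1]) / bin_size_nm)
  ok <- bx >= 0 & bx < nx & by >= 0 & by < ny
  img <- matrix(0L, ny, nx)
  if (any(ok)) {
    tab <- table(by[ok] * nx + bx[ok])
    idx <- as.integer(names(tab))
    img[(idx %% nx) * ny + (idx %/% nx) + 1L] <- as.integer(tab)
  }
  img
}

# 3-point Gaussian peak interpolation along one axis; parabolic fallback
# when a log is undefined.
peak_interp <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0 && (log(cm) + log(cp) - 2 * log(c0)) < 0)
    return(0.5 * (log(cm) - log(cp)) / (log(cm) - 2 * log(c0) + log(cp)))
  den <- cm - 2 * c0 + cp
  if (den < 0) 0.5 * (cm - cp) / den else 0
}

#' Sub-pixel shift between two images by phase correlation
#'
#' Computes the normalised cross-power spectrum, inverts it to a
#' correlation surface, takes the integer peak and refines it with a
#' Gaussian fit over the surrounding 3x3 neighbourhood (per axis,
#' parabolic fallback for non-positive values).
#'
#' @param image_a,image_b Same-shape numeric matrices.
#' @param eps Regularisation added to the cross-power magnitude.
#' @param lowpass_frac Gaussian low-pass applied to the normalised
#'   cross-power (sd as a fraction of the Nyquist frequency). Localization
#'   histograms are sparse, so the raw phase-correlation peak is
#'   delta-like and noise-dominated at high frequencies; the low-pass
#'   turns it into a smooth peak that the Gaussian fit can interpolate.
#' @return Numeric c(dx, dy): shift of \code{image_b} relative to
#'   \code{image_a}, in bins.
#' @export
phase_correlate <- function(image_a, image_b, eps = 1e-8,
                            lowpass_frac = 0.25) {
  stopifnot(all(dim(image_a) == dim(image_b)))
  if (all(image_a == 0) || all(image_b == 0)) stop("all-zero image")
  fa <- stats::fft(image_a)
  fb <- stats::fft(image_b)
  cross <- Conj(fa) * fb
  spec <- cross / (Mod(cross) + eps)
  if (is.finite(lowpass_frac) && lowpass_frac > 0) {
    fy <- fft_freq(nrow(spec)); fx <- fft_freq(ncol(spec))
    w <- exp(-(outer(fy^2, fx^2, `+`)) / (2 * (lowpass_frac * 0.5)^2))
    spec <- spec * w
  }
  r <- Re(stats::fft(spec, inverse = TRUE))
  ny <- nrow(r); nx <- ncol(r)
  pk <- which.max(r)
  py <- ((pk - 1L) %% ny)           # 0-based
  px <- ((pk - 1L) %/% ny)
  wrap <- function(i, n) ((i %% n) + n) %% n + 1L
  cx <- peak_interp(r[py + 1L, wrap(px - 1L, nx)], r[py + 1L, px + 1L],
                    r[py + 1L, wrap(px + 1L, nx)])
  cy <- peak_interp(r[wrap(py - 1L, ny), px + 1L], r[py + 1L, px + 1L],
                    r[wrap(py + 1L, ny), px + 1L])
  # unwrap circular indices to signed shifts
  dx <- if (px > nx / 2) px - nx else px
  dy <- if (py > ny / 2) py - ny else py
  c(dx = dx + cx, dy = dy + cy)
}

#' Fit a per-axis polynomial drift trajectory through batch shifts
#'
#' @param batch_shifts data.frame with columns \code{mid_frame, dx_nm,
#'   dy_nm} holding the cumulative shift of each batch relative to the
#'   first.
#' @param degree Polynomial degree (capped at \code{n_batches - 1}).
#' @param n_frames Movie length; the trajectory is evaluated at every
#'   frame 0..n_frames-1 and anchored to 0 at the first batch midpoint.
#' @return data.frame \code{frame, dx_nm, dy_nm} of class
#'   \code{drift_trajectory}, with the fitted coefficients and the batch
#'   shifts attached as attributes.
#' @export
fit_drift <- function(batch_shifts, degree = 3, n_frames) {
  nb <- nrow(batch_shifts)
  if (degree >= nb) stop("polynomial degree must be below the number of batches")
  stopifnot(nb >= degree + 1)
  # scaled frame variable for conditioning
  sc <- max(n_frames - 1, 1)
  t_b <- batch_shifts$mid_frame / sc
  t_all <- (0:(n_frames - 1)) / sc
  fit_axis <- function(y) {
    cf <- stats::lm.fit(outer(t_b, 0:degree, `^`), y)$coefficients
    cf[is.na(cf)] <- 0
    list(coef = cf, value = drop(outer(t_all, 0:degree, `^`) %*% cf),
         at0 = drop(outer(t_b[1], 0:degree, `^`) %*% cf))
  }
  fx <- fit_axis(batch_shifts$dx_nm)
  fy <- fit_axis(batch_shifts$dy_nm)
  traj <- data.frame(frame = 0:(n_frames - 1),
                     dx_nm = fx$value - fx$at0,
                     dy_nm = fy$value - fy$at0)
  attr(traj, "coef_x") <- fx$coef
  attr(traj, "coef_y") <- fy$coef
  attr(traj, "batch_shifts") <- batch_shifts
  class(traj) <- c("drift_trajectory", "data.frame")
  traj
}

#' Estimate the drift trajectory from the localizations themselves
#'
#' Batches the localizations, builds registered 2D histograms, phase-
#' correlates consecutive batch images, accumulates the relative shifts
#' and interpolates them with a polynomial in the frame index. Uses all
#' fitted localizations, bright or dim.
#'
#' @param locs Localization table.
#' @param n_frames Movie length in frames.
#' @param batch_size Localizations per batch.
#' @param bin_size_nm Histogram bin pitch, nm (about one camera pixel).
#' @param degree Polynomial degree (default 3, capped at batches - 1).
#' @return A \code{drift_trajectory}.
#' @export
estimate_drift <- function(locs, n_frames, batch_size = 1000,
                           bin_size_nm = 100, degree = 3) {
  keep <- if (!is.null(locs$fit_ok)) locs$fit_ok else rep(TRUE, nrow(locs))
  locs <- locs[keep, ]
  batches <- batch_localizations(locs, batch_size)
  extent <- list(xlim = range(locs$x_nm), ylim = range(locs$y_nm))
  imgs <- lapply(batches, histogram_image, bin_size_nm = bin_size_nm,
                 extent = extent)
  nb <- length(batches)
  rel <- matrix(0, nb, 2)
  for (k in 2:nb)
    rel[k, ] <- phase_correlate(imgs[[k - 1]], imgs[[k]]) * bin_size_nm
  mid <- vapply(batches, function(b) mean(range(b$frame)), numeric(1))
  shifts <- data.frame(mid_frame = mid,
                       dx_nm = cumsum(rel[, 1]),
                       dy_nm = cumsum(rel[, 2]))
  fit_drift(shifts, degree = min(degree, nb - 1), n_frames = n_frames)
}

#' Subtract a drift trajectory from localization coordinates
#'
#' @param locs Localization table.
#' @param traj A \code{drift_trajectory} covering every frame in
#'   \code{locs}.
#' @return \code{locs} with corrected \code{x_nm, y_nm}; the uncorrected
#'   coordinates are kept as \code{x_raw_nm, y_raw_nm}.
#' @export
correct_drift <- function(locs, traj) {
  m <- match(locs$frame, traj$frame)
  if (anyNA(m)) stop("trajectory does not cover all frames")
  out <- locs
  if (is.null(out$x_raw_nm)) {
    out$x_raw_nm <- locs$x_nm
    out$y_raw_nm <- locs$y_nm
  }
  out$x_nm <- locs$x_nm - traj$dx_nm[m]
  out$y_nm <- locs$y_nm - traj$dy_nm[m]
  out
}
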