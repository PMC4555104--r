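# Per-frame spot detection: generalized likelihood ratio test of a
# Gaussian PSF over local flat background, then 8-connected particle
# finding.

#' Detection parameters
#'
#' @param psf_sigma_px PSF standard deviation in pixels (default 1.8).
#' @param glrt_sensitivity Threshold on the -2 log likelihood-ratio
#'   statistic; larger values mark fewer pixels. The working range for
#'   this detector is 25-30.
#' @param window_half_size Half-size of the sliding analysis window in
#'   pixels; default \code{ceiling(4 * psf_sigma_px)}, which captures
#'   more than 99 percent of the PSF mass.
#' @return An object of class \code{detection_params}.
#' @export
detection_params <- function(psf_sigma_px = 1.8, glrt_sensitivity = 28,
                             window_half_size = NULL) {
  if (is.null(window_half_size))
    window_half_size <- as.integer(ceiling(4 * psf_sigma_px))
  stopifnot(psf_sigma_px > 0, glrt_sensitivity > 0,
            window_half_size >= ceiling(3 * psf_sigma_px))
  structure(list(psf_sigma_px = psf_sigma_px,
                 glrt_sensitivity = glrt_sensitivity,
                 window_half_size = as.integer(window_half_size)),
            class = "detection_params")
}

# centred pixel-integrated PSF kernel, (2h+1)^2, peak-normalised to 1
glrt_kernel <- function(sigma, half) {
  g1 <- gauss_pixel_integral((-half):half - 0.5, (-half):half + 0.5, 0, sigma)
  k <- outer(g1, g1)
  k / max(k)
}

#' GLRT spot-candidate map
#'
#' For every pixel, compares H1 (a Gaussian spot of known sigma atop a
#' local flat background, amplitude fitted by least squares) against H0
#' (flat background only) in a sliding square window, in the
#' Gaussian-noise approximation. A pixel is marked when the
#' \eqn{-2 \log \Lambda = n \log(SSE_0 / SSE_1)} statistic exceeds
#' \code{glrt_sensitivity} and the fitted amplitude is positive.
#'
#' All window statistics are computed with FFT convolutions; a border of
#' \code{window_half_size} pixels is left unmarked because its windows
#' are incomplete.
#'
#' @param frame 2D numeric matrix of camera counts (rows = y, cols = x).
#' @param params A \code{detection_params}.
#' @param return_statistic If TRUE, return the statistic matrix instead
#'   of the thresholded map.
#' @return Logical matrix of above-threshold pixels (or the numeric
#'   statistic matrix).
#' @export
glrt_map <- function(frame, params, return_statistic = FALSE) {
  stopifnot(inherits(params, "detection_params"),
            is.matrix(frame), all(is.finite(frame)))
  h <- params$window_half_size
  if (nrow(frame) < 2 * h + 1 || ncol(frame) < 2 * h + 1)
    stop("frame smaller than the analysis window")
  k <- glrt_kernel(params$psf_sigma_px, h)
  n <- length(k)
  kc <- k - mean(k)              # mean-removed template
  skk <- sum(kc^2)
  ones <- matrix(1, nrow(k), ncol(k))
  s1 <- fft_convolve2(frame, ones)            # local sum
  s2 <- fft_convolve2(frame^2, ones)          # local sum of squares
  # correlation with the template = convolution with its mirror image;
  # the kernel is symmetric so they coincide
  skI <- fft_convolve2(frame, kc)
  amp <- skI / skk                            # LS amplitude under H1
  sse0 <- pmax(s2 - s1^2 / n, 0)
  sse1 <- pmax(sse0 - amp^2 * skk, .Machine$double.eps * pmax(sse0, 1))
  stat <- ifelse(sse0 > 0, n * log(sse0 / sse1), 0)
  stat[amp <= 0] <- 0
  # incomplete windows at the border
  stat[c(seq_len(h), nrow(stat) - seq_len(h) + 1L), ] <- 0
  stat[, c(seq_len(h), ncol(stat) - seq_len(h) + 1L)] <- 0
  if (return_statistic) return(stat)
  stat > params$glrt_sensitivity
}

#' Group marked pixels into particle candidates
#'
#' Connected components of the binary map under 8-way adjacency; each
#' component yields one candidate at its weighted centroid.
#'
#' @param binary_map Logical matrix from \code{\link{glrt_map}}.
#' @param frame_index Frame number (0-based) recorded with each candidate.
#' @param weights Optional numeric matrix (e.g. the GLRT statistic or the
#'   raw frame) used to weight the centroid; unweighted if NULL.
#' @return data.frame with columns \code{frame, px, py} (pixel
#'   coordinates, 0-based), \code{component_size} and
#'   \code{test_statistic} (max of \code{weights} over the component, NA
#'   if no weights).
#' @export
find_particles <- function(binary_map, frame_index = 0L, weights = NULL) {
  labels <- label_components8(binary_map)
  ncomp <- max(labels)
  if (ncomp == 0L)
    return(data.frame(frame = integer(0), px = numeric(0), py = numeric(0),
                      component_size = integer(0), test_statistic = numeric(0)))
  px <- py <- stat <- numeric(ncomp)
  size <- integer(ncomp)
  nr <- nrow(binary_map)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  r <- ((idx - 1L) %% nr)            # 0-based row = y
  cc <- ((idx - 1L) %/% nr)          # 0-based col = x
  w <- if (is.null(weights)) rep(1, length(idx)) else pmax(weights[idx], 0)
  for (j in seq_len(ncomp)) {
    sel <- lab == j
    wj <- w[sel]
    if (sum(wj) <= 0) wj <- rep(1, sum(sel))
    px[j] <- sum(cc[sel] * wj) / sum(wj)
    py[j] <- sum(r[sel] * wj) / sum(wj)
    size[j] <- sum(sel)
    stat[j] <- if (is.null(weights)) NA_real_ else max(weights[idx][sel])
  }
  data.frame(frame = frame_index, px = px, py = py,
             component_size = size, test_statistic = stat)
}

#' Detect spot candidates in every frame of a movie
#'
#' @param stack A \code{frame_stack}.
#' @param params A \code{detection_params}.
#' @return data.frame of candidates over all frames (see
#'   \code{\link{find_particles}}).
#' @export
detect_movie <- function(stack, params = detection_params()) {
  stopifnot(inherits(stack, "frame_stack"))
  out <- vector("list", length(stack$frames))
  for (f in seq_along(stack$frames)) {
    stat <- glrt_map(stack$frames[[f]], params, return_statistic = TRUE)
    out[[f]] <- find_particles(stat > params$glrt_sensitivity,
                               frame_index = f - 1L, weights = stat)
  }
  do.call(rbind, out)
}
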