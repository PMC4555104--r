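# Internal numerical helpers shared across modules.

# FWHM of a Gaussian is 2*sqrt(2*log(2)) * sigma.
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Convert a Gaussian standard deviation to its full width at half maximum
#'
#' @param sigma Gaussian standard deviation (any length unit).
#' @return FWHM in the same unit, \code{2*sqrt(2*log(2)) * sigma}.
#' @export
sigma_to_fwhm <- function(sigma) FWHM_FACTOR * sigma

#' Convert a full width at half maximum to a Gaussian standard deviation
#'
#' @param fwhm Full width at half maximum (any length unit).
#' @return sigma in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_FACTOR

# Integral of a 1D unit Gaussian (sd = sigma, centre mu) over [lo, hi].
gauss_pixel_integral <- function(lo, hi, mu, sigma) {
  stats::pnorm(hi, mean = mu, sd = sigma) - stats::pnorm(lo, mean = mu, sd = sigma)
}

# Circular 2D convolution via FFT, kernel centred. Returns a matrix the
# same size as x. Kernel must be no larger than x in either dimension.
fft_convolve2 <- function(x, kernel) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr <= nr, kc <= nc)
  kpad <- matrix(0, nr, nc)
  kpad[seq_len(kr), seq_len(kc)] <- kernel
  # centre the kernel at (1,1) so convolution does not translate the image
  cr <- (kr - 1L) %/% 2L
  cc <- (kc - 1L) %/% 2L
  kpad <- kpad[c((cr + 1L):nr, seq_len(cr)), c((cc + 1L):nc, seq_len(cc)), drop = FALSE]
  Re(stats::fft(stats::fft(x) * stats::fft(kpad), inverse = TRUE)) / (nr * nc)
}

# 8-connected component labelling of a logical matrix.
# Returns an integer matrix of labels (0 = background). Implemented as a
# BFS flood fill over the marked pixels; marked sets in this pipeline are
# sparse so this is cheap.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(labels)
  current <- 0L
  # neighbour offsets in (row, col)
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in idx) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue) > 0L) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      cc2 <- ((p - 1L) %/% nr) + 1L
      nbr_r <- r + off_r
      nbr_c <- cc2 + off_c
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      nbr <- (nbr_c[ok] - 1L) * nr + nbr_r[ok]
      nbr <- nbr[mask[nbr] & labels[nbr] == 0L]
      if (length(nbr) > 0L) {
        labels[nbr] <- current
        queue <- c(queue, nbr)
      }
    }
  }
  labels
}

# Normalised FFT sample frequencies (cycles per sample), numpy-style.
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= (n - 1) %/% 2, k, k - n) / n
}

# Draw integers suitable for set.seed() from a user-facing seed, so that
# independent stages of one simulated experiment use decorrelated streams.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream) * 2147483L) %% 2147221L + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
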