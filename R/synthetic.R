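# Synthetic blinking-emitter movies with ground truth.
#
# The generator emulates what a PALM recording of sparse photoconvertible
# emitters looks like: receptor clusters strung along a curved nerve-cord
# path plus isolated background molecules, stochastic photoconversion held
# at a constant rate, on/off blinking ending in photobleaching, and an
# EMCCD-like camera forward model.

#' Camera parameters for the simulated (and analysed) acquisition
#'
#' Defaults follow a typical EMCCD single-molecule setup: 107 nm pixels
#' and a PSF standard deviation of 1.8 pixels.
#'
#' @param pixel_size_nm Size of a camera pixel at the sample, nm.
#' @param psf_sigma_px Standard deviation of the (symmetric Gaussian) PSF,
#'   in pixels.
#' @param frame_interval_s Time between frame starts, seconds.
#' @param em_gain Multiplicative electron-multiplying gain (counts per
#'   photoelectron).
#' @param read_noise Gaussian read noise, counts (standard deviation).
#' @param baseline Camera bias offset, counts.
#' @param background_photons Expected background photons per pixel per
#'   frame (autofluorescence + scattered light).
#' @return An object of class \code{camera_params}.
#' @export
camera_params <- function(pixel_size_nm = 107, psf_sigma_px = 1.8,
                          frame_interval_s = 0.05, em_gain = 1,
                          read_noise = 1, baseline = 100,
                          background_photons = 10) {
  stopifnot(pixel_size_nm > 0, psf_sigma_px > 0, frame_interval_s > 0,
            em_gain > 0, read_noise >= 0, background_photons >= 0)
  structure(list(pixel_size_nm = pixel_size_nm, psf_sigma_px = psf_sigma_px,
                 frame_interval_s = frame_interval_s, em_gain = em_gain,
                 read_noise = read_noise, baseline = baseline,
                 background_photons = background_photons),
            class = "camera_params")
}

#' Photokinetic parameters of the simulated fluorophores
#'
#' Photoconversion is spread uniformly over the movie, which reproduces
#' the effect of ramping the activation laser to keep the number of new
#' conversions per unit time stable. After conversion a molecule emits
#' for a geometric number of frames, then either re-enters a fluorescent
#' state after an exponentially distributed short dark time (blinking) or
#' photobleaches permanently.
#'
#' @param mean_on_frames Expected number of consecutive bright frames per
#'   on-interval.
#' @param blink_dark_mean_s Mean of the exponential short dark time, s.
#'   Must be well below the analysis dark-time threshold (default 10 s)
#'   for blinking correction to work.
#' @param p_blink Probability that a molecule re-enters an on state after
#'   going dark (vs. continuing towards bleaching).
#' @param bleach_after Additional per-exit probability of permanent
#'   bleaching applied on top of \code{1 - p_blink}.
#' @param photons_per_frame_mean,photons_per_frame_sd Mean and standard
#'   deviation of the per-emitter expected photon yield per bright frame
#'   (gamma distributed across emitters). The default puts the peak
#'   signal-to-background-noise ratio of single molecules mostly in the
#'   6-8 range for the default camera.
#' @return An object of class \code{kinetics_params}.
#' @export
kinetics_params <- function(mean_on_frames = 3, blink_dark_mean_s = 0.5,
                            p_blink = 0.3, bleach_after = 0,
                            photons_per_frame_mean = 480,
                            photons_per_frame_sd = 80) {
  stopifnot(mean_on_frames >= 1,
            blink_dark_mean_s >= 0,
            p_blink >= 0, p_blink <= 1,
            bleach_after >= 0, bleach_after <= 1,
            photons_per_frame_mean > 0, photons_per_frame_sd >= 0)
  structure(list(mean_on_frames = mean_on_frames,
                 blink_dark_mean_s = blink_dark_mean_s,
                 p_blink = p_blink, bleach_after = bleach_after,
                 photons_per_frame_mean = photons_per_frame_mean,
                 photons_per_frame_sd = photons_per_frame_sd),
            class = "kinetics_params")
}

#' Phantom layout: clusters along a nerve-cord path plus background
#'
#' @param clusters data.frame with one row per cluster and columns
#'   \code{cx, cy} (centre, nm), \code{sigma_minor, sigma_major}
#'   (Gaussian sd along principal axes, nm), \code{theta} (orientation of
#'   the major axis, radians) and \code{n_molecules}.
#' @param field_size_nm Numeric length 2, field width and height in nm.
#' @param background_density Isolated background molecules per square
#'   micrometre.
#' @param cord_path Optional polyline (matrix with columns x, y in nm)
#'   describing the simulated nerve-cord midline; informational.
#' @return An object of class \code{phantom_layout}.
#' @export
phantom_layout <- function(clusters, field_size_nm, background_density = 0,
                           cord_path = NULL) {
  stopifnot(is.numeric(field_size_nm), length(field_size_nm) == 2,
            all(field_size_nm > 0), background_density >= 0)
  if (is.null(clusters)) {
    clusters <- data.frame(cx = numeric(0), cy = numeric(0),
                           sigma_minor = numeric(0), sigma_major = numeric(0),
                           theta = numeric(0), n_molecules = integer(0))
  }
  need <- c("cx", "cy", "sigma_minor", "sigma_major", "theta", "n_molecules")
  stopifnot(all(need %in% names(clusters)))
  if (nrow(clusters) > 0) {
    stopifnot(all(clusters$sigma_minor <= clusters$sigma_major + 1e-9),
              all(clusters$n_molecules >= 1))
    if (any(sigma_to_fwhm(clusters$sigma_minor) >= 200) ||
        any(sigma_to_fwhm(clusters$sigma_major) >= 450)) {
      warning("cluster sizes exceed the canonical bounds ",
              "(thickness FWHM < 200 nm, length FWHM < 450 nm)")
    }
  }
  structure(list(clusters = clusters, field_size_nm = field_size_nm,
                 background_density = background_density,
                 cord_path = cord_path),
            class = "phantom_layout")
}

#' Default phantom: elongated clusters along a curved cord
#'
#' Draws cluster positions along a gently curved path crossing the field,
#' orients each cluster along the local tangent, and samples per-cluster
#' molecule content from a lognormal whose mean is about 20 molecules per
#' cluster with a heavy tail (sd about 33), so that roughly 9 of 10
#' clusters hold fewer than 50 molecules. Cluster thickness follows the
#' logarithmic thickness-content relation typical of receptor clusters
#' (FWHM about \code{33 ln(n)} nm with scatter, kept below 200 nm), so
#' low-content clusters are compact; length is 1.2-3 times the thickness,
#' capped below 450 nm.
#'
#' @param n_clusters Number of clusters to place.
#' @param field_size_nm Field width and height, nm.
#' @param background_density Background molecules per square micrometre.
#' @param content_meanlog,content_sdlog Lognormal parameters for molecules
#'   per cluster. The defaults give mean about 20.2 and sd about 33.
#' @param seed Integer seed; layout is deterministic given the seed.
#' @return A \code{phantom_layout}.
#' @export
nerve_cord_layout <- function(n_clusters = 10,
                              field_size_nm = c(10000, 10000),
                              background_density = 0.2,
                              content_meanlog = 2.3469,
                              content_sdlog = 1.1479,
                              seed = 1) {
  set.seed(derive_seed(seed, 11L))
  w <- field_size_nm[1]; h <- field_size_nm[2]
  # cord: a sine-perturbed horizontal midline
  tx <- seq(0.08, 0.92, length.out = 200) * w
  ty <- h / 2 + 0.12 * h * sin(2 * pi * tx / w)
  cord <- cbind(x = tx, y = ty)
  # space clusters along the cord with jitter, keep them well inside
  pos_t <- sort(stats::runif(n_clusters, 0.05, 0.95))
  ix <- pmax(1, pmin(200, round(pos_t * 199) + 1))
  cx <- cord[ix, 1] + stats::rnorm(n_clusters, 0, 0.01 * w)
  cy <- cord[ix, 2] + stats::rnorm(n_clusters, 0, 0.02 * h)
  # tangent angle of the cord at each cluster
  theta <- atan2(0.12 * h * 2 * pi / w * cos(2 * pi * cx / w), 1)
  n_mol <- pmax(1L, as.integer(round(stats::rlnorm(n_clusters,
                                                   content_meanlog,
                                                   content_sdlog))))
  # thickness grows logarithmically with content, bounded by 200 nm; the
  # coefficient keeps the core density of a typical cluster clearly above
  # the 4-neighbors-in-50-nm level that the downstream density filter
  # retains (receptor clusters survive that filter; lone molecules do not)
  thick_fwhm <- pmin(pmax(26 * log(n_mol) +
                            stats::rnorm(n_clusters, 0, 5), 40), 195)
  elong <- stats::runif(n_clusters, 1.2, 2.8)
  len_fwhm <- pmin(pmax(thick_fwhm * elong, thick_fwhm), 440)
  clusters <- data.frame(cx = cx, cy = cy,
                         sigma_minor = fwhm_to_sigma(thick_fwhm),
                         sigma_major = fwhm_to_sigma(len_fwhm),
                         theta = theta %% pi,
                         n_molecules = n_mol)
  phantom_layout(clusters, field_size_nm, background_density, cord)
}

#' Draw ground-truth emitter positions from a phantom layout
#'
#' Cluster members are sampled from the rotated bivariate normal of their
#' cluster; background molecules are Poisson-distributed uniformly over
#' the field.
#'
#' @param layout A \code{phantom_layout}.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return data.frame with columns \code{id, x_nm, y_nm, cluster_id}
#'   (\code{NA} for background molecules).
#' @export
build_phantom <- function(layout, seed = 1) {
  stopifnot(inherits(layout, "phantom_layout"))
  if (prod(layout$field_size_nm) <= 0) stop("zero-area field")
  if (layout$background_density < 0) stop("negative background density")
  set.seed(derive_seed(seed, 23L))
  cl <- layout$clusters
  xs <- ys <- numeric(0)
  cid <- integer(0)
  if (nrow(cl) > 0) {
    for (k in seq_len(nrow(cl))) {
      n <- cl$n_molecules[k]
      # principal-axis sample, then rotate by theta (major axis direction)
      u <- stats::rnorm(n, 0, cl$sigma_major[k])
      v <- stats::rnorm(n, 0, cl$sigma_minor[k])
      th <- cl$theta[k]
      xs <- c(xs, cl$cx[k] + u * cos(th) - v * sin(th))
      ys <- c(ys, cl$cy[k] + u * sin(th) + v * cos(th))
      cid <- c(cid, rep.int(k - 1L, n))
    }
  }
  area_um2 <- prod(layout$field_size_nm) / 1e6
  n_bg <- stats::rpois(1, layout$background_density * area_um2)
  if (n_bg > 0) {
    xs <- c(xs, stats::runif(n_bg, 0, layout$field_size_nm[1]))
    ys <- c(ys, stats::runif(n_bg, 0, layout$field_size_nm[2]))
    cid <- c(cid, rep.int(NA_integer_, n_bg))
  }
  data.frame(id = seq_along(xs) - 1L, x_nm = xs, y_nm = ys,
             cluster_id = cid)
}

#' Simulate photoconversion, blinking and bleaching schedules
#'
#' Conversion frames are drawn uniformly over the movie so the number of
#' new activations per unit time has no systematic trend. Each emitter
#' then alternates bright intervals (geometric length, mean
#' \code{mean_on_frames}) with exponential short dark times until it
#' bleaches.
#'
#' @param emitters data.frame from \code{\link{build_phantom}}.
#' @param kinetics A \code{kinetics_params}.
#' @param n_frames Number of frames in the movie.
#' @param frame_interval_s Frame interval, seconds.
#' @param seed Integer seed.
#' @return The emitter data.frame with added columns
#'   \code{conversion_frame}, \code{photons_per_frame} and a list column
#'   \code{on_intervals} (each an integer matrix with columns
#'   \code{start_frame, end_frame}, closed intervals, clipped to the
#'   movie). The continuous dark times drawn (seconds, including those
#'   discretised away) are attached as attribute \code{"dark_times_s"}.
#' @export
simulate_kinetics <- function(emitters, kinetics, n_frames,
                              frame_interval_s = 0.05, seed = 1) {
  stopifnot(inherits(kinetics, "kinetics_params"), n_frames > 0)
  set.seed(derive_seed(seed, 37L))
  n <- nrow(emitters)
  conv <- as.integer(floor(stats::runif(n, 0, n_frames)))
  p_on <- 1 / kinetics$mean_on_frames
  p_cont <- kinetics$p_blink * (1 - kinetics$bleach_after)
  if (kinetics$photons_per_frame_sd > 0) {
    shape <- (kinetics$photons_per_frame_mean / kinetics$photons_per_frame_sd)^2
    photons <- stats::rgamma(n, shape = shape,
                             scale = kinetics$photons_per_frame_mean / shape)
  } else {
    photons <- rep(kinetics$photons_per_frame_mean, n)
  }
  intervals <- vector("list", n)
  dark_all <- numeric(0)
  for (i in seq_len(n)) {
    f <- conv[i]
    iv <- NULL
    repeat {
      len <- 1L + stats::rgeom(1, p_on)
      iv <- rbind(iv, c(f, f + len - 1L))
      if (stats::runif(1) >= p_cont) break
      dark_s <- stats::rexp(1, rate = 1 / kinetics$blink_dark_mean_s)
      dark_all <- c(dark_all, dark_s)
      gap <- max(1L, as.integer(round(dark_s / frame_interval_s)))
      f <- f + len - 1L + gap + 1L
      if (f >= n_frames) break
    }
    # clip to the movie
    iv[, 2] <- pmin(iv[, 2], n_frames - 1L)
    iv <- iv[iv[, 1] <= iv[, 2] & iv[, 1] < n_frames, , drop = FALSE]
    colnames(iv) <- c("start_frame", "end_frame")
    intervals[[i]] <- iv
  }
  out <- emitters
  out$conversion_frame <- conv
  out$photons_per_frame <- photons
  out$on_intervals <- intervals
  attr(out, "dark_times_s") <- dark_all
  attr(out, "frame_interval_s") <- frame_interval_s
  out
}

# pixel weights of an integrated symmetric Gaussian PSF at (x_px, y_px),
# returned as list(ix, iy, w) where w is an outer-product matrix;
# pixel i covers [i - 0.5, i + 0.5) in pixel units.
psf_pixel_weights <- function(x_px, y_px, sigma_px, half, nx, ny) {
  ix <- max(0L, floor(x_px - half)):min(nx - 1L, ceiling(x_px + half))
  iy <- max(0L, floor(y_px - half)):min(ny - 1L, ceiling(y_px + half))
  if (length(ix) == 0L || length(iy) == 0L) return(NULL)
  wx <- gauss_pixel_integral(ix - 0.5, ix + 0.5, x_px, sigma_px)
  wy <- gauss_pixel_integral(iy - 0.5, iy + 0.5, y_px, sigma_px)
  list(ix = ix, iy = iy, w = outer(wy, wx))
}

#' Render a camera movie from scheduled emitters
#'
#' Each bright emitter contributes a pixel-integrated symmetric Gaussian
#' PSF at its (optionally drifted) position. Photon shot noise is
#' Poisson; the camera applies gain, Gaussian read noise and a baseline
#' offset. \code{noise = "emccd"} adds electron-multiplying excess noise
#' via gamma-distributed amplification; \code{"none"} returns the
#' noise-free expectation (useful for oracle checks).
#'
#' @param emitters Output of \code{\link{simulate_kinetics}}.
#' @param camera A \code{camera_params}.
#' @param n_frames Number of frames.
#' @param field_px Integer length 2: frame width and height in pixels.
#' @param drift Optional drift trajectory: data.frame with columns
#'   \code{frame, dx_nm, dy_nm} giving the sample displacement applied in
#'   each frame.
#' @param noise One of \code{"poisson"}, \code{"emccd"}, \code{"none"}.
#' @param seed Integer seed.
#' @return A \code{frame_stack}: list with \code{frames} (list of
#'   ny-by-nx matrices, counts) and \code{camera}.
#' @export
render_movie <- function(emitters, camera, n_frames, field_px,
                         drift = NULL, noise = c("poisson", "emccd", "none"),
                         seed = 1) {
  stopifnot(inherits(camera, "camera_params"),
            !is.null(emitters$on_intervals))
  noise <- match.arg(noise)
  set.seed(derive_seed(seed, 53L))
  nx <- as.integer(field_px[1]); ny <- as.integer(field_px[2])
  pix <- camera$pixel_size_nm
  sig <- camera$psf_sigma_px
  half <- ceiling(4 * sig)
  # frame index (0-based) -> emitter ids on in that frame
  on_at <- vector("list", n_frames)
  for (i in seq_len(nrow(emitters))) {
    iv <- emitters$on_intervals[[i]]
    if (is.null(iv) || nrow(iv) == 0) next
    for (r in seq_len(nrow(iv))) {
      fr <- iv[r, 1]:iv[r, 2]
      fr <- fr[fr >= 0 & fr < n_frames]
      for (f in fr) on_at[[f + 1L]] <- c(on_at[[f + 1L]], i)
    }
  }
  if (!is.null(drift)) {
    stopifnot(all(c("frame", "dx_nm", "dy_nm") %in% names(drift)))
    dx <- drift$dx_nm[match(0:(n_frames - 1L), drift$frame)]
    dy <- drift$dy_nm[match(0:(n_frames - 1L), drift$frame)]
    if (anyNA(dx) || anyNA(dy)) stop("drift trajectory must cover all frames")
  } else {
    dx <- dy <- rep(0, n_frames)
  }
  n_clipped <- 0L
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    photons <- matrix(camera$background_photons, ny, nx)
    for (i in on_at[[f]]) {
      x_px <- (emitters$x_nm[i] + dx[f]) / pix
      y_px <- (emitters$y_nm[i] + dy[f]) / pix
      pw <- psf_pixel_weights(x_px, y_px, sig, half, nx, ny)
      if (is.null(pw)) { n_clipped <- n_clipped + 1L; next }
      photons[pw$iy + 1L, pw$ix + 1L] <-
        photons[pw$iy + 1L, pw$ix + 1L] + emitters$photons_per_frame[i] * pw$w
    }
    counts <- switch(noise,
      none = camera$em_gain * photons,
      poisson = {
        pe <- stats::rpois(length(photons), photons)
        camera$em_gain * pe +
          stats::rnorm(length(photons), 0, camera$read_noise)
      },
      emccd = {
        pe <- stats::rpois(length(photons), photons)
        amp <- numeric(length(pe))
        nz <- pe > 0
        amp[nz] <- stats::rgamma(sum(nz), shape = pe[nz],
                                 scale = camera$em_gain)
        amp + stats::rnorm(length(photons), 0, camera$read_noise)
      })
    frames[[f]] <- matrix(pmax(0, counts + camera$baseline), ny, nx)
  }
  if (n_clipped > 0L)
    message(n_clipped, " emitter-frame contributions fell outside the field")
  structure(list(frames = frames, camera = camera, n_clipped = n_clipped),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_stack: %d frames of %d x %d px (%.0f nm/px, %.3f s/frame)\n",
              length(x$frames), d[2], d[1],
              x$camera$pixel_size_nm, x$camera$frame_interval_s))
  invisible(x)
}

#' Write / read ground-truth emitter tables
#'
#' Plain-text CSV; the per-emitter on-interval list is JSON-encoded in a
#' single column so the table round-trips losslessly.
#'
#' @param emitters Emitter data.frame (with schedules).
#' @param path File path.
#' @return \code{read_ground_truth} returns the emitter data.frame.
#' @export
write_ground_truth <- function(emitters, path) {
  df <- emitters
  df$on_intervals <- vapply(emitters$on_intervals, function(iv) {
    jsonlite::toJSON(unname(apply(iv, 1, function(r) r, simplify = FALSE)))
  }, character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$on_intervals <- lapply(df$on_intervals, function(s) {
    m <- jsonlite::fromJSON(s)
    if (is.list(m)) m <- do.call(rbind, m)
    m <- matrix(as.integer(m), ncol = 2,
                dimnames = list(NULL, c("start_frame", "end_frame")))
    m
  })
  df
}
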