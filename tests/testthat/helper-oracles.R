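# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use different algorithms from the package code
# they check.

# brute-force all-pairs density filter (O(n^2) distance matrix)
oracle_density_filter <- function(points, radius, min_neighbors,
                                  keep_neighbors = TRUE) {
  n <- nrow(points)
  if (n == 0) return(logical(0))
  d <- as.matrix(stats::dist(points[, c("x_nm", "y_nm")]))
  within <- d <= radius
  diag(within) <- FALSE
  core <- unname(rowSums(within) >= min_neighbors)
  if (!keep_neighbors) return(core)
  unname(core | apply(within, 1, function(w) any(w & core)))
}

# ray-casting point-in-polygon (counts crossings of a ray going up)
oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- vx[i]; y1 <- vy[i]; x2 <- vx[j]; y2 <- vy[j]
    if ((x1 <= px) != (x2 <= px)) {
      ycross <- y1 + (px - x1) * (y2 - y1) / (x2 - x1)
      if (ycross > py) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# single-emitter movie: one permanently-on emitter at (x_px, y_px)
single_spot_stack <- function(x_px, y_px, photons = 500, n_frames = 1,
                              field = 25, camera = camera_params(),
                              noise = "none", seed = 1) {
  em <- data.frame(id = 0L, x_nm = x_px * camera$pixel_size_nm,
                   y_nm = y_px * camera$pixel_size_nm,
                   cluster_id = NA_integer_,
                   conversion_frame = 0L, photons_per_frame = photons)
  em$on_intervals <- list(matrix(c(0L, n_frames - 1L), 1,
                                 dimnames = list(NULL, c("start_frame",
                                                         "end_frame"))))
  list(emitters = em,
       stack = render_movie(em, camera, n_frames, c(field, field),
                            noise = noise, seed = seed))
}

# pseudo-localization table straight from a kinetics schedule: one row
# per bright frame at the true position plus isotropic jitter
locs_from_schedule <- function(emitters, jitter_nm = 10, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(emitters)), function(i) {
    iv <- emitters$on_intervals[[i]]
    if (is.null(iv) || nrow(iv) == 0) return(NULL)
    fr <- unlist(lapply(seq_len(nrow(iv)), function(r) iv[r, 1]:iv[r, 2]))
    data.frame(frame = fr,
               x_nm = emitters$x_nm[i] + rnorm(length(fr), 0, jitter_nm),
               y_nm = emitters$y_nm[i] + rnorm(length(fr), 0, jitter_nm),
               precision_nm = 20, fit_ok = TRUE)
  })
  out <- do.call(rbind, rows)
  out$id <- seq_len(nrow(out)) - 1L
  out
}

# clustered localization table with injected drift, for drift tests
drifted_locs <- function(n = 6000, n_frames = 10000, n_clusters = 12,
                         drift_fun_x = function(t) 400 * t^2,
                         drift_fun_y = function(t) -300 * t + 100 * t^2,
                         seed = 7) {
  set.seed(seed)
  cx <- runif(n_clusters, 1000, 9000)
  cy <- runif(n_clusters, 1000, 9000)
  k <- sample(n_clusters, n, replace = TRUE)
  fr <- sort(sample(0:(n_frames - 1), n, replace = TRUE))
  t <- fr / (n_frames - 1)
  list(locs = data.frame(frame = fr,
                         x_nm = cx[k] + rnorm(n, 0, 60) + drift_fun_x(t) +
                           rnorm(n, 0, 20),
                         y_nm = cy[k] + rnorm(n, 0, 40) + drift_fun_y(t) +
                           rnorm(n, 0, 20),
                         fit_ok = TRUE),
       true_dx = drift_fun_x((0:(n_frames - 1)) / (n_frames - 1)),
       true_dy = drift_fun_y((0:(n_frames - 1)) / (n_frames - 1)))
}

# rotated bivariate normal sample
rotated_cluster <- function(n, cx, cy, s_minor, s_major, theta, seed = 1) {
  set.seed(seed)
  u <- rnorm(n, 0, s_major); v <- rnorm(n, 0, s_minor)
  data.frame(x_nm = cx + u * cos(theta) - v * sin(theta),
             y_nm = cy + u * sin(theta) + v * cos(theta))
}
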