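# Cluster morphometry: freely rotating anisotropic 2D Gaussian fit of
# each contoured group of molecules, FWHM thickness/length, and the
# population summaries (content statistics, thickness/length vs content
# logarithmic fits).

#' ROI polygon
#'
#' @param vertices Matrix (or data.frame) with columns x, y in nm; the
#'   polygon is closed implicitly. Needs at least 3 vertices.
#' @param label Character label.
#' @return An object of class \code{roi_polygon}.
#' @export
roi_polygon <- function(vertices, label = "roi") {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2, nrow(v) >= 3, all(is.finite(v)))
  colnames(v) <- c("x", "y")
  structure(list(vertices = v, label = label), class = "roi_polygon")
}

# even-odd point-in-polygon; boundary points count as inside
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary check: point on segment (i, j)
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    within <- px >= pmin(xi, xj) - 1e-9 & px <= pmax(xi, xj) + 1e-9 &
              py >= pmin(yi, yj) - 1e-9 & py <= pmax(yi, yj) + 1e-9
    scale <- pmax(abs(xj - xi), abs(yj - yi), 1)
    on_edge <- on_edge | (abs(cross) <= 1e-9 * scale & within)
    # even-odd ray crossing (horizontal ray towards +x)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Select the points inside an ROI polygon
#'
#' Even-odd containment test; points exactly on the boundary are
#' included.
#'
#' @param points data.frame with \code{x_nm, y_nm}.
#' @param roi A \code{roi_polygon}.
#' @return The rows of \code{points} inside the polygon.
#' @export
select_in_roi <- function(points, roi) {
  stopifnot(inherits(roi, "roi_polygon"))
  v <- roi$vertices
  if (nrow(unique(v)) < 3) stop("degenerate polygon")
  keep <- point_in_polygon(points$x_nm, points$y_nm, v[, 1], v[, 2])
  points[keep, , drop = FALSE]
}

#' Propose ROI polygons around dense molecule groups
#'
#' Automates the operator's contouring for testing: molecules are binned
#' on a grid, occupied bins are grouped under 8-connectivity, and every
#' component holding at least \code{min_count} molecules is contoured by
#' the convex hull of its molecules dilated by one grid cell.
#'
#' @param points Molecule table (\code{x_nm, y_nm}).
#' @param grid_nm Bin pitch of the occupancy grid, nm.
#' @param min_count Minimum molecules per proposed ROI.
#' @return List of \code{roi_polygon}.
#' @export
propose_rois <- function(points, grid_nm = 100, min_count = 5) {
  stopifnot(grid_nm > 0)
  if (nrow(points) == 0) return(list())
  bx <- floor(points$x_nm / grid_nm)
  by <- floor(points$y_nm / grid_nm)
  x0 <- min(bx); y0 <- min(by)
  nx <- max(bx) - x0 + 1L; ny <- max(by) - y0 + 1L
  occ <- matrix(FALSE, ny, nx)
  occ[cbind(by - y0 + 1L, bx - x0 + 1L)] <- TRUE
  labels <- label_components8(occ)
  comp <- labels[cbind(by - y0 + 1L, bx - x0 + 1L)]
  out <- list()
  for (k in seq_len(max(labels))) {
    rows <- which(comp == k)
    if (length(rows) < min_count) next
    px <- points$x_nm[rows]; py <- points$y_nm[rows]
    # dilate by one grid cell: hull over each point's surrounding square
    ex <- c(px - grid_nm, px + grid_nm, px - grid_nm, px + grid_nm)
    ey <- c(py - grid_nm, py - grid_nm, py + grid_nm, py + grid_nm)
    h <- grDevices::chull(ex, ey)
    out[[length(out) + 1L]] <-
      roi_polygon(cbind(ex[h], ey[h]),
                  label = sprintf("roi_%03d", length(out) + 1L))
  }
  out
}

#' Fit a freely rotating anisotropic 2D Gaussian to a molecule cluster
#'
#' Maximum-likelihood bivariate Gaussian of the molecule coordinates:
#' centre = sample mean, axes and orientation from the
#' eigendecomposition of the (ML, 1/n) covariance. The two standard
#' deviations are not coupled and the orientation is free. Sizes are
#' reported as FWHM; the smaller one is the cluster thickness, the
#' larger the cluster length. Clusters thinner than
#' \code{resolution_nm} are flagged \code{retained = FALSE}, as are
#' degenerate (collinear) clusters.
#'
#' @param points data.frame with \code{x_nm, y_nm}; at least 5 rows.
#' @param label Cluster label.
#' @param resolution_nm Discard threshold on thickness (default 25 nm,
#'   a typical dataset-average localization precision).
#' @return One-row data.frame: \code{label, n_molecules, x_nm, y_nm,
#'   sigma_min_nm, sigma_max_nm, theta_rad, thickness_nm, length_nm,
#'   retained}.
#' @export
fit_cluster <- function(points, label = "cluster", resolution_nm = 25) {
  n <- nrow(points)
  if (n < 5) stop("cluster fitting requires at least 5 molecules")
  x <- points$x_nm; y <- points$y_nm
  cx <- mean(x); cy <- mean(y)
  # ML covariance (1/n)
  sxx <- mean((x - cx)^2); syy <- mean((y - cy)^2)
  sxy <- mean((x - cx) * (y - cy))
  ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2, 2), symmetric = TRUE)
  s_max <- sqrt(max(ev$values[1], 0))
  s_min <- sqrt(max(ev$values[2], 0))
  theta <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi
  thickness <- sigma_to_fwhm(s_min)
  len <- sigma_to_fwhm(s_max)
  data.frame(label = label, n_molecules = n, x_nm = cx, y_nm = cy,
             sigma_min_nm = s_min, sigma_max_nm = s_max,
             theta_rad = theta, thickness_nm = thickness, length_nm = len,
             retained = is.finite(thickness) && thickness >= resolution_nm)
}

#' Fit every proposed/contoured cluster of a dataset
#'
#' @param points Molecule table.
#' @param rois List of \code{roi_polygon}; ROIs holding fewer than 5
#'   molecules are skipped with a warning.
#' @param resolution_nm Passed to \code{\link{fit_cluster}}.
#' @return data.frame of cluster fits (possibly 0 rows).
#' @export
analyze_clusters <- function(points, rois, resolution_nm = 25) {
  fits <- list()
  for (roi in rois) {
    inside <- select_in_roi(points, roi)
    if (nrow(inside) < 5) {
      warning("ROI '", roi$label, "' holds fewer than 5 molecules; skipped")
      next
    }
    fits[[length(fits) + 1L]] <-
      fit_cluster(inside, label = roi$label, resolution_nm = resolution_nm)
  }
  if (length(fits) == 0)
    return(fit_cluster(data.frame(x_nm = rnorm(5), y_nm = rnorm(5)))[0, ])
  do.call(rbind, fits)
}

#' Population summary of cluster fits
#'
#' Discarded (non-retained) fits are excluded from the statistics but
#' counted. Thickness-vs-content and length-vs-content relations are
#' fitted with \code{y = a ln(x) + b} by least squares.
#'
#' @param fits data.frame of cluster fits.
#' @return list with \code{n_clusters}, \code{n_discarded_small},
#'   \code{content_mean}, \code{content_sd}, \code{content_max},
#'   \code{frac_below_50}, and \code{thickness_fit} / \code{length_fit}
#'   (named coefficients a, b).
#' @export
summarize_clusters <- function(fits) {
  if (nrow(fits) == 0) stop("no cluster fits")
  keep <- fits[fits$retained, ]
  if (nrow(keep) == 0) stop("all cluster fits were discarded")
  logfit <- function(y) {
    cf <- stats::coef(stats::lm(y ~ log(keep$n_molecules)))
    c(a = unname(cf[2]), b = unname(cf[1]))
  }
  list(n_clusters = nrow(fits),
       n_discarded_small = sum(!fits$retained),
       content_mean = mean(keep$n_molecules),
       content_sd = stats::sd(keep$n_molecules),
       content_max = max(keep$n_molecules),
       frac_below_50 = mean(keep$n_molecules < 50),
       thickness_fit = logfit(keep$thickness_nm),
       length_fit = logfit(keep$length_nm))
}
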