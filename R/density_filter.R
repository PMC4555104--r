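# Neighbor-count density filter: removes non-clustered single-molecule
# noise while retaining cluster cores and their edges.

#' Density filter parameters
#'
#' A point is a core point if it has at least \code{min_neighbors} other
#' points within \code{radius_nm} (inclusive boundary; a point is not its
#' own neighbor). With \code{keep_neighbors} every point within the
#' radius of a core point is retained too, so the edges of small clusters
#' survive.
#'
#' @param radius_nm Neighborhood radius, nm (default 50, i.e. 0.05 um).
#' @param min_neighbors Minimum neighbor count for a core point.
#' @param keep_neighbors Retain all neighbors of core points.
#' @return An object of class \code{filter_params}.
#' @export
filter_params <- function(radius_nm = 50, min_neighbors = 4,
                          keep_neighbors = TRUE) {
  stopifnot(radius_nm > 0, min_neighbors >= 1)
  structure(list(radius_nm = radius_nm,
                 min_neighbors = as.integer(min_neighbors),
                 keep_neighbors = isTRUE(keep_neighbors)),
            class = "filter_params")
}

# neighbor counts within radius via a uniform grid (cell list); returns
# for each point the number of *other* points within r (inclusive), and
# optionally whether it lies within r of any point flagged in `of`.
grid_neighbors <- function(x, y, r, of = NULL) {
  n <- length(x)
  cellx <- floor(x / r); celly <- floor(y / r)
  key <- paste(cellx, celly)
  cells <- split(seq_len(n), key)
  count <- integer(n)
  near_core <- logical(n)
  r2 <- r * r
  for (cell in names(cells)) {
    ij <- as.numeric(strsplit(cell, " ", fixed = TRUE)[[1]])
    here <- cells[[cell]]
    nbr <- here
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      k <- paste(ij[1] + dx, ij[2] + dy)
      if (!is.null(cells[[k]])) nbr <- c(nbr, cells[[k]])
    }
    for (i in here) {
      d2 <- (x[nbr] - x[i])^2 + (y[nbr] - y[i])^2
      within <- d2 <= r2
      count[i] <- sum(within) - 1L       # exclude the point itself
      if (!is.null(of)) near_core[i] <- any(within & of[nbr])
    }
  }
  list(count = count, near_core = near_core)
}

#' Remove sparse localization noise by neighbor counting
#'
#' @param points data.frame with \code{x_nm, y_nm} (molecule or
#'   localization table).
#' @param params A \code{filter_params}.
#' @return list with \code{retained} and \code{removed} data.frames
#'   (input order preserved) and the logical vector \code{keep}.
#' @export
filter_outliers <- function(points, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  n <- nrow(points)
  if (n == 0)
    return(list(retained = points, removed = points, keep = logical(0)))
  x <- points$x_nm; y <- points$y_nm
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  nb <- grid_neighbors(x, y, params$radius_nm)
  core <- nb$count >= params$min_neighbors
  keep <- core
  if (params$keep_neighbors && any(core)) {
    nb2 <- grid_neighbors(x, y, params$radius_nm, of = core)
    keep <- core | nb2$near_core
  }
  list(retained = points[keep, , drop = FALSE],
       removed = points[!keep, , drop = FALSE],
       keep = keep)
}
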