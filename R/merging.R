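# Consolidation of repeated detections of one fluorophore:
# consecutive-frame linking, dark-time tolerant re-linking of blinking
# molecules, and the dark-time diagnostic curve used to choose t_d.

#' Merging parameters
#'
#' "Same location" is operationalised as within \code{capture_radius_nm}
#' (localization jitter makes exact coordinate equality measure-zero);
#' the default is one camera pixel. The allowed dark time can be given in
#' seconds (\code{t_d_s}, converted via \code{frame_interval_s}) or
#' directly in frames (\code{off_gap_frames}).
#'
#' @param capture_radius_nm Linking radius, nm.
#' @param t_d_s Allowed dark time between serial occurrences, seconds
#'   (default 10).
#' @param frame_interval_s Frame interval, seconds.
#' @param off_gap_frames Optional: dark time in frames; overrides
#'   \code{t_d_s} (e.g. 200 frames).
#' @return An object of class \code{merge_params}.
#' @export
merge_params <- function(capture_radius_nm = 107, t_d_s = 10,
                         frame_interval_s = 0.05, off_gap_frames = NULL) {
  stopifnot(capture_radius_nm > 0, t_d_s >= 0, frame_interval_s > 0)
  if (is.null(off_gap_frames))
    off_gap_frames <- t_d_s / frame_interval_s
  else
    t_d_s <- off_gap_frames * frame_interval_s
  structure(list(capture_radius_nm = capture_radius_nm, t_d_s = t_d_s,
                 frame_interval_s = frame_interval_s,
                 off_gap_frames = off_gap_frames),
            class = "merge_params")
}

# empty molecule table
empty_molecules <- function() {
  data.frame(molecule_id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
             first_frame = integer(0), last_frame = integer(0),
             n_detections = integer(0), weight = numeric(0),
             max_gap_frames = integer(0))
}

#' Link detections appearing at the same location in consecutive frames
#'
#' Greedy frame-by-frame tracker: a localization in frame f joins the
#' track whose most recent localization (in frame f-1) lies within the
#' capture radius; the nearest candidate wins and each localization joins
#' at most one track, so a slowly wandering spot chains into one track
#' even when its first and last appearances are far apart. Spots in the
#' same frame never merge. The reported molecule position is the
#' precision-weighted mean of all member localizations.
#'
#' @param locs Drift-corrected localization table (\code{frame, x_nm,
#'   y_nm}; \code{precision_nm} used for weighting when present).
#' @param params A \code{merge_params}.
#' @return Molecule table: \code{molecule_id, x_nm, y_nm, first_frame,
#'   last_frame, n_detections, weight, max_gap_frames}, plus a list
#'   column \code{members} of localization row ids.
#' @export
link_consecutive <- function(locs, params = merge_params()) {
  if (!is.null(locs$fit_ok)) locs <- locs[locs$fit_ok, ]
  n <- nrow(locs)
  if (n == 0) { m <- empty_molecules(); m$members <- list(); return(m) }
  if (is.null(locs$id)) locs$id <- seq_len(n) - 1L
  w_all <- if (!is.null(locs$precision_nm) &&
               all(is.finite(locs$precision_nm)) &&
               all(locs$precision_nm > 0))
    1 / locs$precision_nm^2 else rep(1, n)
  ord <- order(locs$frame)
  locs <- locs[ord, ]; w_all <- w_all[ord]
  r2 <- params$capture_radius_nm^2
  # growing track state
  tx <- ty <- tw <- numeric(0)     # weighted sums and weights
  lx <- ly <- numeric(0)           # most recent member position
  tfirst <- tlast <- integer(0)
  tn <- integer(0)
  tmembers <- list()
  active <- integer(0)             # tracks whose last frame == previous frame
  frames <- unique(locs$frame)
  rows_by_frame <- split(seq_len(n), locs$frame)
  prev_frame <- -2L
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    rows <- rows_by_frame[[fi]]
    active <- if (f == prev_frame + 1L) which(tlast == prev_frame) else integer(0)
    taken <- logical(length(active))
    # assign nearest-candidate first: order all (loc, track) pairs by distance
    if (length(active) > 0L) {
      ax <- lx[active]
      ay <- ly[active]
      cand <- NULL
      for (j in seq_along(rows)) {
        d2 <- (locs$x_nm[rows[j]] - ax)^2 + (locs$y_nm[rows[j]] - ay)^2
        ok <- which(d2 <= r2)
        if (length(ok) > 0L)
          cand <- rbind(cand, cbind(j = j, a = ok, d2 = d2[ok]))
      }
      assigned <- rep(NA_integer_, length(rows))
      if (!is.null(cand)) {
        cand <- cand[order(cand[, "d2"]), , drop = FALSE]
        for (rr in seq_len(nrow(cand))) {
          j <- cand[rr, "j"]; a <- cand[rr, "a"]
          if (is.na(assigned[j]) && !taken[a]) {
            assigned[j] <- a
            taken[a] <- TRUE
          }
        }
      }
    } else {
      assigned <- rep(NA_integer_, length(rows))
    }
    for (j in seq_along(rows)) {
      i <- rows[j]
      wi <- w_all[i]
      if (!is.na(assigned[j])) {
        t <- active[assigned[j]]
        tx[t] <- tx[t] + wi * locs$x_nm[i]
        ty[t] <- ty[t] + wi * locs$y_nm[i]
        tw[t] <- tw[t] + wi
        lx[t] <- locs$x_nm[i]; ly[t] <- locs$y_nm[i]
        tlast[t] <- f
        tn[t] <- tn[t] + 1L
        tmembers[[t]] <- c(tmembers[[t]], locs$id[i])
      } else {
        tx <- c(tx, wi * locs$x_nm[i]); ty <- c(ty, wi * locs$y_nm[i])
        tw <- c(tw, wi)
        lx <- c(lx, locs$x_nm[i]); ly <- c(ly, locs$y_nm[i])
        tfirst <- c(tfirst, f); tlast <- c(tlast, f); tn <- c(tn, 1L)
        tmembers[[length(tx)]] <- locs$id[i]
      }
    }
    prev_frame <- f
  }
  out <- data.frame(molecule_id = seq_along(tx) - 1L,
                    x_nm = tx / tw, y_nm = ty / tw,
                    first_frame = tfirst, last_frame = tlast,
                    n_detections = tn, weight = tw,
                    max_gap_frames = 0L)
  out$members <- tmembers
  out
}

#' Merge blinking molecules separated by short dark times
#'
#' Molecules within the capture radius whose temporal gap (frames between
#' the disappearance of the earlier and the reappearance of the later,
#' converted to seconds) is at most \code{t_d_s} are merged transitively,
#' earliest first. Ties are broken by smaller spatial distance, then
#' lower molecule id, so the output is deterministic.
#'
#' @param molecules Output of \code{\link{link_consecutive}}.
#' @param params A \code{merge_params}.
#' @return Molecule table in the same format; positions are the
#'   weight-combined means of the merged parts.
#' @export
link_blinking <- function(molecules, params = merge_params()) {
  n <- nrow(molecules)
  if (n <= 1) return(molecules)
  gap_max <- params$off_gap_frames
  r2 <- params$capture_radius_nm^2
  ord <- order(molecules$first_frame, molecules$molecule_id)
  m <- molecules[ord, ]
  # open merged molecules, processed in order of appearance
  gx <- m$x_nm * m$weight; gy <- m$y_nm * m$weight
  gw <- m$weight
  gfirst <- m$first_frame; glast <- m$last_frame
  gn <- m$n_detections
  gmember <- m$members
  ggap <- rep(0L, n)
  alive <- rep(TRUE, n)
  # spatial hash (cell size = capture radius) over group member positions;
  # a group is registered under every cell it received a member in, and
  # candidate lookup scans the 5x5 cell neighbourhood, which covers every
  # group whose running mean can lie within the capture radius.
  r <- params$capture_radius_nm
  cellx <- as.integer(floor(m$x_nm / r))
  celly <- as.integer(floor(m$y_nm / r))
  cells <- new.env(parent = emptyenv(), hash = TRUE)
  ckey <- function(cx, cy) paste(cx, cy)
  register <- function(j, cx, cy) {
    k <- ckey(cx, cy)
    cells[[k]] <- c(cells[[k]], j)
  }
  register(1L, cellx[1], celly[1])
  for (i in 2:n) {
    fi <- m$first_frame[i]
    js <- integer(0)
    for (ox in -2:2) for (oy in -2:2) {
      hit <- cells[[ckey(cellx[i] + ox, celly[i] + oy)]]
      if (!is.null(hit)) js <- c(js, hit)
    }
    js <- unique(js[js < i])
    # earlier groups that disappeared within the allowed dark time
    js <- js[alive[js] & glast[js] <= fi - 1L &
               glast[js] >= fi - 1L - gap_max]
    best <- 0L
    if (length(js) > 0L) {
      d2 <- (m$x_nm[i] - gx[js] / gw[js])^2 +
            (m$y_nm[i] - gy[js] / gw[js])^2
      js <- js[d2 <= r2]; d2 <- d2[d2 <= r2]
      if (length(js) > 0L) {
        # earliest-appearing group wins; ties by distance, then id
        o <- order(gfirst[js], d2, js)
        best <- js[o[1]]
      }
    }
    if (best == 0L) register(i, cellx[i], celly[i])
    if (best > 0L) {
      j <- best
      register(j, cellx[i], celly[i])
      ggap[j] <- max(ggap[j], m$first_frame[i] - glast[j] - 1L)
      gx[j] <- gx[j] + m$x_nm[i] * m$weight[i]
      gy[j] <- gy[j] + m$y_nm[i] * m$weight[i]
      gw[j] <- gw[j] + m$weight[i]
      glast[j] <- max(glast[j], m$last_frame[i])
      gn[j] <- gn[j] + m$n_detections[i]
      gmember[[j]] <- c(gmember[[j]], m$members[[i]])
      alive[i] <- FALSE
    }
  }
  keep <- which(alive)
  out <- data.frame(molecule_id = seq_along(keep) - 1L,
                    x_nm = gx[keep] / gw[keep], y_nm = gy[keep] / gw[keep],
                    first_frame = gfirst[keep], last_frame = glast[keep],
                    n_detections = gn[keep], weight = gw[keep],
                    max_gap_frames = ggap[keep])
  out$members <- gmember[keep]
  out
}

#' Dark-time diagnostic curve
#'
#' Counts the unique molecules obtained after blinking-merge at each
#' allowed dark time in \code{t_d_grid}, and fits the biphasic model
#' \deqn{N(t_d) = A e^{-t_d/\tau} + B - C t_d} whose fast component is
#' fluorophore blinking and whose slow linear component is coincidental
#' merging of distinct molecules.
#'
#' @param molecules Pre-blink-merge molecule table (from
#'   \code{\link{link_consecutive}}).
#' @param t_d_grid Ascending dark times in seconds, at least 5 values.
#' @param params A \code{merge_params} (its \code{t_d_s} is overridden by
#'   each grid value).
#' @return list with \code{curve} (data.frame \code{t_d_s, n_molecules}),
#'   \code{fit} (named coefficients A, tau, B, C or NULL),
#'   \code{tau_s}, \code{plateau_onset_s} (dark time beyond which the
#'   fitted fast component has decayed to 5 percent) and \code{fit_ok}.
#' @export
dark_time_curve <- function(molecules, t_d_grid, params = merge_params()) {
  stopifnot(length(t_d_grid) >= 5, !is.unsorted(t_d_grid))
  counts <- vapply(t_d_grid, function(td) {
    if (td <= 0) return(nrow(molecules))
    p <- merge_params(capture_radius_nm = params$capture_radius_nm,
                      t_d_s = td, frame_interval_s = params$frame_interval_s)
    nrow(link_blinking(molecules, p))
  }, numeric(1))
  curve <- data.frame(t_d_s = t_d_grid, n_molecules = counts)
  fit <- tryCatch({
    a0 <- max(counts[1] - min(counts), 1)
    tau0 <- max(t_d_grid[which(counts - min(counts) <=
                                 a0 * exp(-1))[1]], t_d_grid[2])
    nl <- stats::nls(n_molecules ~ A * exp(-t_d_s / tau) + B - C * t_d_s,
                     data = curve,
                     start = list(A = a0, tau = tau0,
                                  B = min(counts), C = 0),
                     control = stats::nls.control(maxiter = 200,
                                                  warnOnly = TRUE))
    stats::coef(nl)
  }, error = function(e) NULL)
  fit_ok <- !is.null(fit) && is.finite(fit[["tau"]]) && fit[["tau"]] > 0
  list(curve = curve,
       fit = fit,
       tau_s = if (fit_ok) fit[["tau"]] else NA_real_,
       plateau_onset_s = if (fit_ok) 3 * fit[["tau"]] else NA_real_,
       fit_ok = fit_ok)
}
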