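test_that("select_in_roi keeps interior and boundary points", {
  roi <- roi_polygon(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
  pts <- data.frame(x_nm = c(50, 99, 1, 150, -10),
                    y_nm = c(50, 1, 99, 50, 50))
  expect_equal(nrow(select_in_roi(pts, roi)), 3)
  # boundary point is included
  edge <- data.frame(x_nm = c(100, 50), y_nm = c(50, 0))
  expect_equal(nrow(select_in_roi(edge, roi)), 2)
  expect_error(roi_polygon(cbind(c(0, 1), c(0, 1))))
})

test_that("containment matches a ray-casting oracle on random polygons", {
  set.seed(12)
  for (rep in 1:10) {
    nv <- sample(3:9, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 200, 900)
    vx <- 1000 + rad * cos(ang)
    vy <- 1000 + rad * sin(ang)
    roi <- roi_polygon(cbind(vx, vy))
    px <- runif(100, 0, 2000); py <- runif(100, 0, 2000)
    got <- ccpalm:::point_in_polygon(px, py, vx, vy)
    want <- vapply(seq_along(px),
                   function(i) oracle_point_in_polygon(px[i], py[i], vx, vy),
                   logical(1))
    # oracle is boundary-agnostic; exclude near-boundary points
    d <- vapply(seq_along(px), function(i)
      min(sqrt((vx - px[i])^2 + (vy - py[i])^2)), numeric(1))
    interior <- d > 1
    expect_equal(got[interior], want[interior])
  }
})

test_that("propose_rois separates well-spaced clusters", {
  a <- rotated_cluster(30, 1000, 1000, 30, 80, 0.4, seed = 5)
  b <- rotated_cluster(25, 3000, 1000, 25, 60, 1.2, seed = 6)
  rois <- propose_rois(rbind(a, b), grid_nm = 100, min_count = 5)
  expect_length(rois, 2)
  pts <- rbind(a, b)
  n_in <- vapply(rois, function(r) nrow(select_in_roi(pts, r)), numeric(1))
  expect_equal(sort(n_in), c(25, 30))
  expect_length(propose_rois(a[0, ], 100, 5), 0)
})

test_that("fit_cluster recovers a rotated anisotropic Gaussian", {
  pts <- rotated_cluster(10000, 1500, -700, 30, 90, 30 * pi / 180,
                         seed = 42)
  f <- fit_cluster(pts)
  expect_equal(f$sigma_min_nm, 30, tolerance = 0.05)
  expect_equal(f$sigma_max_nm, 90, tolerance = 0.05)
  expect_lt(abs(f$theta_rad - 30 * pi / 180) * 180 / pi, 2)
  expect_equal(f$thickness_nm, 2 * sqrt(2 * log(2)) * f$sigma_min_nm)
  expect_equal(f$length_nm, 2 * sqrt(2 * log(2)) * f$sigma_max_nm)
  expect_true(f$thickness_nm <= f$length_nm)
  expect_true(f$retained)
})

test_that("degenerate and symmetric clusters are handled", {
  # 5 collinear points: zero thickness, discarded
  line <- data.frame(x_nm = (0:4) * 50, y_nm = (0:4) * 25)
  f <- fit_cluster(line)
  expect_equal(f$thickness_nm, 0, tolerance = 1e-9)
  expect_false(f$retained)
  # points on a circle: both FWHMs equal
  th <- 2 * pi * (0:11) / 12
  circ <- data.frame(x_nm = 100 * cos(th), y_nm = 100 * sin(th))
  fc <- fit_cluster(circ)
  expect_equal(fc$thickness_nm, fc$length_nm, tolerance = 1e-6)
  expect_error(fit_cluster(line[1:4, ]), "at least 5")
})

test_that("fit_cluster is translation-invariant and rotation-equivariant", {
  pts <- rotated_cluster(3000, 0, 0, 40, 100, 0.7, seed = 8)
  f0 <- fit_cluster(pts)
  shifted <- transform(pts, x_nm = x_nm + 5000, y_nm = y_nm - 3000)
  f1 <- fit_cluster(shifted)
  expect_equal(f1$sigma_min_nm, f0$sigma_min_nm)
  expect_equal(f1$sigma_max_nm, f0$sigma_max_nm)
  expect_equal(f1$theta_rad, f0$theta_rad)
  phi <- 0.9
  rot <- data.frame(x_nm = pts$x_nm * cos(phi) - pts$y_nm * sin(phi),
                    y_nm = pts$x_nm * sin(phi) + pts$y_nm * cos(phi))
  f2 <- fit_cluster(rot)
  expect_equal(f2$sigma_max_nm, f0$sigma_max_nm)
  dtheta <- (f2$theta_rad - f0$theta_rad) %% pi
  expect_equal(min(dtheta, pi - dtheta), min(phi %% pi, pi - phi %% pi),
               tolerance = 1e-6)
})

test_that("summarize_clusters computes the population statistics", {
  mk <- function(n, th, len, retained = TRUE)
    data.frame(label = "c", n_molecules = n, x_nm = 0, y_nm = 0,
               sigma_min_nm = th / 2.3548, sigma_max_nm = len / 2.3548,
               theta_rad = 0, thickness_nm = th, length_nm = len,
               retained = retained)
  fits <- rbind(mk(20, 80, 160), mk(21, 90, 170), mk(8, 10, 30, FALSE))
  s <- summarize_clusters(fits)
  expect_equal(s$n_clusters, 3)
  expect_equal(s$n_discarded_small, 1)
  expect_equal(s$content_mean, 20.5)
  expect_equal(s$frac_below_50, 1)
  # exact recovery of a noiseless logarithmic relation
  ns <- c(6, 10, 20, 50, 120)
  fits2 <- do.call(rbind, lapply(ns, function(n)
    mk(n, 40 * log(n) + 5, 60 * log(n) + 10)))
  s2 <- summarize_clusters(fits2)
  expect_equal(unname(s2$thickness_fit["a"]), 40, tolerance = 1e-8)
  expect_equal(unname(s2$thickness_fit["b"]), 5, tolerance = 1e-8)
  expect_equal(unname(s2$length_fit["a"]), 60, tolerance = 1e-8)
  expect_error(summarize_clusters(fits[0, ]), "no cluster")
})

test_that("phantom cluster populations respect the size bounds", {
  lay <- nerve_cord_layout(n_clusters = 40, field_size_nm = c(40000, 8000),
                           background_density = 0, seed = 2)
  fwhm_minor <- 2.3548 * lay$clusters$sigma_minor
  fwhm_major <- 2.3548 * lay$clusters$sigma_major
  expect_true(all(fwhm_minor < 200))
  expect_true(all(fwhm_major < 450))
  # content heavy-tailed with mean near 20 and ~90 percent below 50
  lay2 <- nerve_cord_layout(n_clusters = 4000,
                            field_size_nm = c(400000, 50000),
                            background_density = 0, seed = 3)
  n <- lay2$clusters$n_molecules
  expect_gt(mean(n), 16)
  expect_lt(mean(n), 25)
  expect_gt(mean(n < 50), 0.85)
  expect_lt(mean(n < 50), 0.97)
})
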