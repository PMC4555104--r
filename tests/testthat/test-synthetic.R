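test_that("build_phantom places exactly the requested cluster molecules", {
  lay <- phantom_layout(data.frame(cx = 2000, cy = 2000, sigma_minor = 30,
                                   sigma_major = 90, theta = 0.3,
                                   n_molecules = 20),
                        field_size_nm = c(5000, 5000),
                        background_density = 0)
  em <- build_phantom(lay, seed = 3)
  expect_equal(nrow(em), 20)
  expect_true(all(em$cluster_id == 0L))
  # deterministic for a fixed seed
  expect_identical(em, build_phantom(lay, seed = 3))
  expect_false(identical(em$x_nm, build_phantom(lay, seed = 4)$x_nm))
})

test_that("background molecule counts are Poisson-consistent", {
  lay <- phantom_layout(NULL, field_size_nm = c(10000, 10000),
                        background_density = 1)
  counts <- vapply(1:120, function(s) nrow(build_phantom(lay, seed = s)),
                   numeric(1))
  # mean 100, variance 100 for Poisson(100)
  expect_gt(mean(counts), 100 - 3 * 10 / sqrt(120))
  expect_lt(mean(counts), 100 + 3 * 10 / sqrt(120))
  disp <- var(counts) / mean(counts)   # dispersion index ~ 1
  expect_gt(disp, 0.6)
  expect_lt(disp, 1.6)
  em <- build_phantom(lay, seed = 1)
  expect_true(all(is.na(em$cluster_id)))
  expect_true(all(em$x_nm >= 0 & em$x_nm <= 10000))
})

test_that("phantom layout validates geometry", {
  expect_error(build_phantom(phantom_layout(NULL, c(0, 100)), 1),
               "field")
  expect_warning(
    phantom_layout(data.frame(cx = 0, cy = 0, sigma_minor = 100,
                              sigma_major = 300, theta = 0, n_molecules = 5),
                   c(1000, 1000)),
    "bounds")
})

test_that("kinetics: no blinking means exactly one on-interval", {
  em <- data.frame(id = 0:199, x_nm = runif(200, 0, 1e4),
                   y_nm = runif(200, 0, 1e4), cluster_id = NA)
  sim <- simulate_kinetics(em, kinetics_params(p_blink = 0), 5000,
                           0.05, seed = 2)
  expect_true(all(vapply(sim$on_intervals, nrow, integer(1)) == 1L))
})

test_that("kinetics: blink re-entry gives geometric interval counts", {
  em <- data.frame(id = seq_len(12000) - 1L, x_nm = 0, y_nm = 0,
                   cluster_id = NA)
  sim <- simulate_kinetics(em,
                           kinetics_params(p_blink = 0.5,
                                           blink_dark_mean_s = 0.5),
                           n_frames = 100000, 0.05, seed = 5)
  ni <- vapply(sim$on_intervals, nrow, integer(1))
  # geometric with success 0.5 -> mean 2; se ~ sqrt(2)/100
  expect_gt(mean(ni), 2 - 4 * sqrt(2) / 100)
  expect_lt(mean(ni), 2 + 4 * sqrt(2) / 100)
  # short dark times are exponential with the configured mean
  dk <- attr(sim, "dark_times_s")
  expect_gt(length(dk), 1e4 - 1)
  expect_gt(stats::ks.test(dk, "pexp", 1 / 0.5)$p.value, 0.01)
})

test_that("kinetics: activation rate has no temporal trend", {
  em <- data.frame(id = seq_len(20000) - 1L, x_nm = 0, y_nm = 0,
                   cluster_id = NA)
  sim <- simulate_kinetics(em, kinetics_params(), 10000, 0.05, seed = 9)
  per_frame <- tabulate(sim$conversion_frame + 1L, 10000)
  fit <- summary(stats::lm(per_frame ~ seq_along(per_frame)))
  expect_gt(fit$coefficients[2, 4], 0.01)   # slope not significant
  # intervals respect the conversion frame and are disjoint + ordered
  ok <- vapply(seq_len(200), function(i) {
    iv <- sim$on_intervals[[i]]
    all(iv[, 1] >= sim$conversion_frame[i]) &&
      all(iv[, 2] >= iv[, 1]) &&
      (nrow(iv) < 2 || all(iv[-1, 1] > iv[-nrow(iv), 2]))
  }, logical(1))
  expect_true(all(ok))
})

test_that("render_movie: empty forward model gives flat baseline frames", {
  cam <- camera_params(read_noise = 0, background_photons = 0)
  em <- data.frame(id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                   cluster_id = integer(0), conversion_frame = integer(0),
                   photons_per_frame = numeric(0))
  em$on_intervals <- list()
  st <- render_movie(em, cam, 3, c(12, 12), seed = 1)
  for (f in st$frames) expect_true(all(f == cam$baseline))
})

test_that("render_movie: noise-free photon sum matches the closed form", {
  cam <- camera_params(em_gain = 30, read_noise = 0, background_photons = 2)
  fx <- single_spot_stack(10.3, 9.6, photons = 700, field = 21,
                          camera = cam, noise = "none")
  fr <- fx$stack$frames[[1]]
  total_above_baseline <- sum(fr - cam$baseline)
  expected <- cam$em_gain * (700 + 2 * 21 * 21)
  expect_equal(total_above_baseline, expected, tolerance = 1e-3)
  # argmax pixel is the emitter's pixel
  pk <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk["col"]) - 1L, 10L)  # x = 10.3 -> pixel 10
  expect_equal(unname(pk["row"]) - 1L, 10L)  # y = 9.6  -> pixel 10
})

test_that("render_movie is bit-identical for identical seeds", {
  lay <- phantom_layout(data.frame(cx = 1000, cy = 1000, sigma_minor = 30,
                                   sigma_major = 60, theta = 1,
                                   n_molecules = 10),
                        c(2140, 2140), background_density = 0.5)
  em <- build_phantom(lay, seed = 6)
  em <- simulate_kinetics(em, kinetics_params(), 50, 0.05, seed = 6)
  s1 <- render_movie(em, camera_params(), 50, c(20, 20), seed = 8)
  s2 <- render_movie(em, camera_params(), 50, c(20, 20), seed = 8)
  expect_identical(s1$frames, s2$frames)
})

test_that("ground-truth tables round-trip through CSV + JSON intervals", {
  lay <- phantom_layout(data.frame(cx = 500, cy = 500, sigma_minor = 20,
                                   sigma_major = 50, theta = 0,
                                   n_molecules = 6),
                        c(1000, 1000))
  em <- build_phantom(lay, seed = 1)
  em <- simulate_kinetics(em, kinetics_params(), 200, 0.05, seed = 1)
  p <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(em, p)
  back <- read_ground_truth(p)
  expect_equal(back$x_nm, em$x_nm)
  expect_equal(back$conversion_frame, em$conversion_frame)
  for (i in seq_len(nrow(em)))
    expect_equal(unname(back$on_intervals[[i]]),
                 unname(em$on_intervals[[i]]))
})
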