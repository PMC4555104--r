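mp <- merge_params(capture_radius_nm = 107, t_d_s = 10,
                   frame_interval_s = 0.05)

test_that("merge_params converts between seconds and frames", {
  expect_equal(mp$off_gap_frames, 200)
  alt <- merge_params(frame_interval_s = 0.05, off_gap_frames = 200)
  expect_equal(alt$t_d_s, 10)
})

test_that("consecutive-frame appearances collapse to one molecule", {
  locs <- data.frame(frame = c(10L, 11L, 12L), x_nm = c(500, 510, 495),
                     y_nm = c(300, 305, 298), fit_ok = TRUE)
  m <- link_consecutive(locs, mp)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_detections, 3L)
  expect_equal(m$first_frame, 10L)
  expect_equal(m$last_frame, 12L)
  # unweighted mean when no precision column present
  expect_equal(m$x_nm, mean(locs$x_nm))
})

test_that("same-frame spots never merge", {
  locs <- data.frame(frame = c(5L, 5L), x_nm = c(0, 214), y_nm = c(0, 0),
                     fit_ok = TRUE)
  expect_equal(nrow(link_consecutive(locs, mp)), 2)
})

test_that("greedy chaining keeps a-b-c together even when a-c is far", {
  # consecutive pairs within radius; track mean stays within reach
  locs <- data.frame(frame = c(0L, 1L, 2L),
                     x_nm = c(0, 100, 160), y_nm = c(0, 0, 0),
                     fit_ok = TRUE)
  # brute-force expectation: b joins a (d = 100 <= 107); track mean moves
  # to 50; c at 160 is within 107 of the updated mean (110) -> one track
  m <- link_consecutive(locs, mp)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_detections, 3L)
})

test_that("precision weighting dominates the track position", {
  locs <- data.frame(frame = c(0L, 1L), x_nm = c(0, 100), y_nm = c(0, 0),
                     precision_nm = c(5, 50), fit_ok = TRUE)
  m <- link_consecutive(locs, mp)
  w <- 1 / c(5, 50)^2
  expect_equal(m$x_nm, sum(w * locs$x_nm) / sum(w))
})

test_that("dark gaps up to t_d merge, beyond t_d split", {
  # appearances every 1 s (20 frames), t_d = 10 s
  locs <- data.frame(frame = c(0L, 20L, 40L), x_nm = 10, y_nm = 10,
                     fit_ok = TRUE)
  m <- link_blinking(link_consecutive(locs, mp), mp)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_detections, 3L)
  expect_equal(m$max_gap_frames, 19L)
  # 11 s gap (221 frames between appearances): 220 dark frames > 200
  far <- data.frame(frame = c(0L, 221L), x_nm = 10, y_nm = 10,
                    fit_ok = TRUE)
  expect_equal(nrow(link_blinking(link_consecutive(far, mp), mp)), 2)
  # exactly 200 dark frames still merges (threshold inclusive)
  at <- data.frame(frame = c(0L, 201L), x_nm = 10, y_nm = 10,
                   fit_ok = TRUE)
  expect_equal(nrow(link_blinking(link_consecutive(at, mp), mp)), 1)
})

test_that("blinking merge is transitive and earliest-first", {
  # chain: appearances at 0, 100, 200 -- each gap below 200 frames
  locs <- data.frame(frame = c(0L, 100L, 200L), x_nm = c(0, 50, 100),
                     y_nm = 0, fit_ok = TRUE)
  m <- link_blinking(link_consecutive(locs, mp), mp)
  expect_equal(nrow(m), 1)
  expect_equal(m$first_frame, 0L)
  expect_equal(m$last_frame, 200L)
})

test_that("detection counts are conserved through both merge stages", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 400
    locs <- data.frame(frame = sample(0:500, n, replace = TRUE),
                       x_nm = runif(n, 0, 3000), y_nm = runif(n, 0, 3000),
                       precision_nm = runif(n, 10, 30), fit_ok = TRUE)
    m1 <- link_consecutive(locs, mp)
    expect_equal(sum(m1$n_detections), n)
    m2 <- link_blinking(m1, mp)
    expect_equal(sum(m2$n_detections), n)
    expect_lte(nrow(m2), nrow(m1))
    # member ids partition the input
    expect_equal(sort(unlist(m2$members)), 0:(n - 1L))
  }
})

test_that("a noise-free blinking schedule is recovered exactly", {
  set.seed(3)
  nmol <- 300
  em <- data.frame(id = 1:nmol - 1L, x_nm = runif(nmol, 0, 50000),
                   y_nm = runif(nmol, 0, 50000), cluster_id = NA)
  sim <- simulate_kinetics(em,
                           kinetics_params(p_blink = 0.5,
                                           blink_dark_mean_s = 0.5),
                           n_frames = 8000, 0.05, seed = 6)
  locs <- locs_from_schedule(sim, jitter_nm = 10, seed = 6)
  m <- link_blinking(link_consecutive(locs, mp), mp)
  expect_equal(nrow(m), nmol)
})

test_that("dark-time curve is monotone and finds the blink timescale", {
  # full-scale flatness check (<1 percent beyond 2 s over 1e4 emitters)
  # lives in test-acceptance.R; this is a fast small-n version
  set.seed(3)
  nmol <- 500
  em <- data.frame(id = 1:nmol - 1L, x_nm = runif(nmol, 0, 80000),
                   y_nm = runif(nmol, 0, 80000), cluster_id = NA)
  sim <- simulate_kinetics(em, kinetics_params(), # default blinking
                           n_frames = 8000, 0.05, seed = 6)
  locs <- locs_from_schedule(sim, jitter_nm = 10, seed = 6)
  pre <- link_consecutive(locs, mp)
  grid <- c(0, 0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 10)
  dtc <- dark_time_curve(pre, grid, mp)
  expect_equal(dtc$curve$n_molecules[1], nrow(pre))  # t_d = 0: no merging
  expect_true(all(diff(dtc$curve$n_molecules) <= 0))
  expect_true(dtc$fit_ok)
  expect_gt(dtc$tau_s, 0.25)
  expect_lt(dtc$tau_s, 1.0)
  # curve ends at (or very near) the true emitter count
  expect_lt(abs(dtc$curve$n_molecules[13] - nmol) / nmol, 0.02)
})
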