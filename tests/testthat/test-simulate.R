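noise_free <- function(n_frames = 100) {
  acquisition_params(n_frames = n_frames, localization_noise = c(0, 0, 0))
}

test_that("degenerate and free Brownian trajectories match closed-form moments", {
  tr <- simulate_trajectory("free", 0, acq = noise_free(50), seed = 1)
  expect_true(all(tr$x == tr$x[1] & tr$y == tr$y[1] & tr$z == tr$z[1]))

  # mean squared 3D step = 6 D dt; per-axis increment variance = 2 D dt
  d0 <- 0.05
  acq <- acquisition_params(n_frames = 100001, frame_interval = 0.05,
                            localization_noise = c(0, 0, 0))
  tr <- simulate_trajectory("free", d0, acq = acq, seed = 2)
  stepsq <- diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2
  expect_equal(mean(stepsq), 6 * d0 * 0.05, tolerance = 0.02)
  for (v in list(diff(tr$x), diff(tr$y), diff(tr$z))) {
    expect_equal(var(v), 2 * d0 * 0.05, tolerance = 0.03)
  }
})

test_that("confined trajectories obey the geometric bound and MSD plateau", {
  acq <- noise_free(3000)
  tr <- simulate_trajectory("confined", 0.01, radius = 0.1, acq = acq,
                            seed = 3)
  pos <- attr(tr, "true_positions")
  expect_lte(max(dist(pos)), 0.2)
  # long-time plateau of reflected Brownian motion in a sphere: <= (6/5) r^2
  mc <- msd(tr, max_lag = 500, frame_interval = 0.05)
  plateau <- mean(mc$msd[mc$lag > 200], na.rm = TRUE)
  expect_lte(plateau, 1.2 * 0.1^2 * 1.1)
  expect_gt(plateau, 0.5 * 1.2 * 0.1^2)
})

test_that("trajectory generators are deterministic given the seed", {
  a <- simulate_trajectory("confined", 0.004, radius = 0.15,
                           acq = noise_free(40), seed = 9)
  b <- simulate_trajectory("confined", 0.004, radius = 0.15,
                           acq = noise_free(40), seed = 9)
  expect_identical(a, b)
})

test_that("population composition matches the preset fractions", {
  sc <- make_scene(6, c(20, 20, 1), seed = 1)
  acq <- acquisition_params(n_frames = 12)

  # boundary: no fast fraction -> everything confined
  p <- population_preset("sqd_sa")
  p$fraction_fast <- 0
  p$synaptic_fraction <- 1
  pop0 <- simulate_population(p, sc, 200, acq, seed = 1)
  expect_true(all(pop0$truth$kind == "confined"))

  pop <- simulate_population("bqd_day1", sc, 4000, acq, seed = 2)
  f <- mean(pop$truth$kind == "free")
  expect_lt(abs(f - 0.73), 3 * sqrt(0.73 * 0.27 / 4000))

  pop <- simulate_population("sqd_sa", sc, 4000, acq, seed = 3)
  s <- mean(pop$truth$synaptic)
  expect_lt(abs(s - 0.75), 3 * sqrt(0.75 * 0.25 / 4000))
  # confined synaptic tracks are attached to nanodomain centers
  syn <- pop$truth[pop$truth$synaptic, ]
  nd <- as.matrix(sc$nanodomains[, c("x", "y", "z")])
  ctr <- as.matrix(syn[, c("center_x", "center_y", "center_z")])
  hit <- vapply(seq_len(nrow(ctr)), function(i) {
    min(sqrt(rowSums(sweep(nd, 2, ctr[i, ])^2))) < 1e-9
  }, logical(1))
  expect_true(all(hit))

  expect_error(simulate_population("no_such_probe", sc, 10, acq),
               "unknown preset")
})

test_that("homer PALM tables have centroids at PSD centers and respect seeds", {
  sc <- make_scene(1, c(8, 8, 1), seed = 5)
  tab <- simulate_homer_palm(sc, locs_per_cluster = 500, sigma_cluster = 0.05,
                             background_density = 0, seed = 2)
  expect_equal(nrow(tab), 500)
  ctr <- colMeans(tab[, c("x", "y")])
  expect_lt(sqrt(sum((ctr - sc$psd_centers[1, 1:2])^2)),
            3 * 0.05 / sqrt(500) * sqrt(2))

  # zero clusters -> background only
  sc0 <- sc
  sc0$psd_centers <- sc$psd_centers[0, , drop = FALSE]
  bg <- simulate_homer_palm(sc0, 500, background_density = 3, seed = 2)
  expect_true(all(bg$cluster == 0))

  expect_identical(simulate_homer_palm(sc, 100, seed = 7),
                   simulate_homer_palm(sc, 100, seed = 7))
  expect_error(simulate_homer_palm(sc, 100, background_density = -1),
               "background_density")
})

test_that("fiducial traces are grid + drift + noise", {
  acq <- acquisition_params(n_frames = 20)
  zero <- matrix(0, 20, 3)
  f <- simulate_fiducials(zero, n_fiducials = 4, noise = 0, acq = acq)
  spread <- tapply(f$table$x, f$table$fiducial, function(v) diff(range(v)))
  expect_true(all(spread == 0))

  # linear drift 10 nm/min -> 50 nm over 5 min, exactly, before noise
  acq5 <- acquisition_params(frame_interval = 1, n_frames = 301)
  lin <- function(t) c(0.01 / 60 * t, 0, 0)
  f <- simulate_fiducials(lin, n_fiducials = 1, noise = 0, acq = acq5)
  x <- f$table$x
  expect_equal(x[301] - x[1], 0.05, tolerance = 1e-12)

  # variance of the mean across 25 fiducials: noise^2 / 25 per frame
  acqn <- acquisition_params(n_frames = 400)
  f <- simulate_fiducials(matrix(0, 400, 3), n_fiducials = 25, noise = 0.005,
                          acq = acqn, seed = 3)
  per_frame_mean <- tapply(f$table$x - rep(f$grid[, 1], each = 400),
                           f$table$frame, mean)
  expect_equal(var(per_frame_mean), 0.005^2 / 25, tolerance = 0.25)
})

test_that("nanohole pairs carry the field displacement exactly", {
  null_field <- function(xy, z = 0) matrix(0, nrow(xy), 2)
  nh <- simulate_nanohole_pair(1.5, null_field, loc_noise = 0,
                               grid_extent = c(5, 5), seed = 1)
  expect_equal(nh$ch1$x, nh$ch2$x)
  expect_equal(nh$ch1$y, nh$ch2$y)

  shift80 <- function(xy, z = 0) {
    cbind(rep(0.08, nrow(xy)), rep(0, nrow(xy)))
  }
  nh <- simulate_nanohole_pair(1.5, shift80, loc_noise = 0,
                               grid_extent = c(4, 4), seed = 1)
  d <- sqrt((nh$ch2$x - nh$ch1$x)^2 + (nh$ch2$y - nh$ch1$y)^2)
  expect_equal(d, rep(0.08, 16))

  a <- simulate_nanohole_pair(1.5, distortion_field(seed = 3), 0.001,
                              c(6, 6), seed = 5)
  b <- simulate_nanohole_pair(1.5, distortion_field(seed = 3), 0.001,
                              c(6, 6), seed = 5)
  expect_identical(a, b)
  expect_error(simulate_nanohole_pair(0, grid_extent = c(5, 5)))
})
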