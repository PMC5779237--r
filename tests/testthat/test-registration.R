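test_that("drift is recovered exactly from a single noiseless fiducial", {
  acq <- acquisition_params(n_frames = 50)
  dr <- cbind(seq(0, 0.049, length.out = 50), 0.02 * sin(1:50 / 8), 0)
  fid <- simulate_fiducials(dr, n_fiducials = 1, noise = 0, acq = acq)
  est <- estimate_drift(fid, smoothing_window = 1)
  rel <- sweep(dr, 2, dr[1, ])
  expect_equal(est$dx, rel[, 1], tolerance = 1e-10)
  expect_equal(est$dy, rel[, 2], tolerance = 1e-10)
  expect_equal(est$dx[1], 0)
})

test_that("injected linear drift slope is recovered within the regression CI", {
  acq <- acquisition_params(n_frames = 600)
  slope <- 0.01 / 60  # 10 nm / min in um/s
  lin <- function(t) c(slope * t, 0, 0)
  fid <- simulate_fiducials(lin, 25, noise = 0.005, acq = acq, seed = 2)
  est <- estimate_drift(fid, smoothing_window = 10)
  t <- (est$frame - 1) * acq$frame_interval
  fit <- lm(est$dx ~ t)
  expect_equal(unname(coef(fit)["t"]), slope, tolerance = 0.02)
})

test_that("static-pattern drift estimate has ~1 nm residual with 25 fiducials", {
  acq <- acquisition_params(n_frames = 600)
  fid <- simulate_fiducials(matrix(0, 600, 3), 25, noise = 0.005, acq = acq,
                            seed = 3)
  est <- estimate_drift(fid, smoothing_window = 10)
  expect_lt(sqrt(mean(c(est$dx^2, est$dy^2))), 0.0015)
})

test_that("drift correction is exact arithmetic and conserves records", {
  loc <- data.frame(frame = rep(1:5, 3), x = runif(15), y = runif(15),
                    z = runif(15))
  zero <- data.frame(frame = 1:5, dx = 0, dy = 0, dz = 0)
  expect_equal(apply_drift_correction(loc, zero), loc)

  dr <- data.frame(frame = 1:5, dx = 0.01 * (0:4), dy = 0, dz = 0)
  once <- apply_drift_correction(loc, dr)
  expect_equal(nrow(once), nrow(loc))
  twice <- apply_drift_correction(once, dr)
  expect_equal(twice$x, loc$x - 2 * dr$dx[match(loc$frame, dr$frame)])

  expect_error(apply_drift_correction(data.frame(frame = 9, x = 1, y = 1), dr),
               "outside the drift trace")
})

test_that("drift correction reduces the temporal variance of static emitters", {
  acq <- acquisition_params(n_frames = 300)
  drift_mat <- cbind(0.05 * sin((1:300) / 40), 0.04 * cos((1:300) / 55), 0)
  fid <- simulate_fiducials(drift_mat, 9, noise = 0.005, acq = acq, seed = 5)
  est <- estimate_drift(fid, 10)
  # a static emitter observed under the same drift
  loc <- data.frame(frame = 1:300,
                    x = 3 + drift_mat[, 1] + rnorm(300, sd = 0.005),
                    y = 3 + drift_mat[, 2] + rnorm(300, sd = 0.005))
  corr <- apply_drift_correction(loc, est)
  expect_lt(var(corr$x), var(loc$x))
  expect_lt(var(corr$y), var(loc$y))
})

test_that("chromatic map recovers identity and affine distortions exactly", {
  g <- expand.grid(x = seq(-10, 10, 2), y = seq(-10, 10, 2))
  id_pairs <- data.frame(x1 = g$x, y1 = g$y, x2 = g$x, y2 = g$y)
  mp <- fit_chromatic_map(id_pairs, degree = 2, seed = 1)
  out <- apply_map(data.frame(x = c(-3, 5), y = c(2, 7)), mp)
  expect_equal(out$x, c(-3, 5), tolerance = 1e-9)
  expect_equal(out$y, c(2, 7), tolerance = 1e-9)
  expect_lt(mp$residual_rms, 1e-9)

  # pure affine distortion, degree >= 1, noiseless: exact recovery
  aff <- data.frame(x1 = g$x, y1 = g$y,
                    x2 = 0.05 + 1.001 * g$x - 0.002 * g$y,
                    y2 = -0.03 + 0.0015 * g$x + 0.999 * g$y)
  mp1 <- fit_chromatic_map(aff, degree = 1, seed = 2)
  expect_lt(mp1$residual_rms, 1e-9)

  expect_error(fit_chromatic_map(id_pairs[1:4, ], degree = 2),
               "at least")
  coll <- data.frame(x1 = 1:20, y1 = 2 * (1:20), x2 = 1:20, y2 = 2 * (1:20))
  expect_error(fit_chromatic_map(coll, degree = 2), "degenerate")
})

test_that("held-out chromatic residual meets the 2 nm margin on nanohole grids", {
  nh <- simulate_nanohole_pair(1.5, distortion_field(0.08, extent = 30,
                                                     seed = 4),
                               loc_noise = 0.001, grid_extent = c(40, 40),
                               seed = 5)
  # the simulated offset really is ~80 nm
  expect_equal(sqrt(mean(rowSums(nh$true_displacement^2))), 0.08,
               tolerance = 0.15)
  mp <- fit_chromatic_map(nh, degree = 2, seed = 1)
  expect_lte(mp$residual_rms, 0.002)
})

test_that("held-out residual does not increase from degree 1 to 2 on smooth fields", {
  nh <- simulate_nanohole_pair(1.5, distortion_field(0.08, extent = 30,
                                                     seed = 8),
                               loc_noise = 0.001, grid_extent = c(25, 25),
                               seed = 9)
  r1 <- fit_chromatic_map(nh, degree = 1, seed = 1)$residual_rms
  r2 <- fit_chromatic_map(nh, degree = 2, seed = 1)$residual_rms
  expect_lte(r2, r1 * 1.05)
})

test_that("apply_map preserves counts, flags z validity, checks channels", {
  g <- expand.grid(x = seq(-6, 6, 2), y = seq(-6, 6, 2))
  mp <- fit_chromatic_map(data.frame(x1 = g$x, y1 = g$y, x2 = g$x, y2 = g$y),
                          degree = 1, seed = 1)
  loc <- data.frame(x = c(0, 1), y = c(0, 1), z = c(0.1, 0.6), channel = 1)
  out <- apply_map(loc, mp, channel = 1)
  expect_equal(nrow(out), 2)
  expect_equal(out$map_valid, c(TRUE, FALSE))
  expect_error(apply_map(loc, mp, channel = 2), "channel mismatch")
})

test_that("fitted map corrects a weakly z-dependent field to ~4 nm at |z| = 400 nm", {
  fld <- distortion_field(0.08, extent = 30, z_gradient = 0.005, seed = 6)
  nh0 <- simulate_nanohole_pair(1.5, fld, 0.001, c(25, 25), z = 0, seed = 7)
  mp <- fit_chromatic_map(nh0, degree = 2, seed = 1)
  nh4 <- simulate_nanohole_pair(1.5, fld, 0.001, c(25, 25), z = 0.4, seed = 8)
  mapped <- apply_map(data.frame(x = nh4$ch1$x, y = nh4$ch1$y), mp)
  resid <- sqrt(mean((mapped$x - nh4$ch2$x)^2 + (mapped$y - nh4$ch2$y)^2))
  expect_lte(resid, 0.004)
})
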