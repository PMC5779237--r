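psf <- psf_model()
analytic_cal <- local({
  zg <- seq(-0.4, 0.4, by = 0.02)
  build_z_calibration(data.frame(z = zg, wx = psf$wx(zg), wy = psf$wy(zg)))
})

test_that("rendered spots integrate to the requested photon count and are symmetric in focus", {
  em <- data.frame(frame = 1, x = 1.6, y = 1.6, z = 0)
  st <- render_frames(em, psf, c(32, 32), photons = 4000, background = 0,
                      noiseless = TRUE)
  expect_equal(sum(st[, , 1]), 4000, tolerance = 1e-6)
  # symmetric spot at z = 0: image equals its transpose about the emitter
  ft <- fit_spot(st[, , 1], pixel_size = 0.1)
  expect_equal(ft$wx, ft$wy, tolerance = 1e-6)
  expect_error(render_frames(data.frame(frame = 1, x = 99, y = 1, z = 0),
                             psf, c(32, 32)), "outside field")
})

test_that("detection finds isolated spots and nothing on blank frames", {
  blank <- matrix(5, 24, 24)
  expect_equal(nrow(detect_spots(blank, 50)), 0)
  expect_error(detect_spots(matrix(numeric(0), 0, 0), 1), "empty frame")

  em <- data.frame(frame = 1, x = c(0.8, 2.4), y = c(1.2, 1.2),
                   z = c(0, 0))
  st <- render_frames(em, psf, c(32, 32), photons = 4000, background = 10,
                      read_noise = 2, seed = 4)
  cand <- detect_spots(st[, , 1], 60, min_separation = 3)
  expect_equal(nrow(cand), 2)
  # each candidate within one pixel of a true emitter
  for (i in 1:2) {
    expect_lt(min(abs(cand$x - em$x[i]) + abs(cand$y - em$y[i])), 0.2)
  }
  # two emitters far apart give two disjoint maxima
  em2 <- data.frame(frame = 1, x = c(1, 6), y = c(1, 6), z = 0)
  st2 <- render_frames(em2, psf, c(80, 80), photons = 4000, background = 0,
                       noiseless = TRUE)
  expect_equal(nrow(detect_spots(st2[, , 1], 10, 3)), 2)
})

test_that("elliptical Gaussian fitting recovers noiseless ground truth", {
  em <- data.frame(frame = 1, x = 1.07, y = 0.93, z = 0.15)
  st <- render_frames(em, psf, c(21, 21), photons = 5000, background = 3,
                      noiseless = TRUE)
  ft <- fit_spot(st[, , 1], pixel_size = 0.1)
  expect_true(ft$converged)
  expect_lt(abs(ft$x - 1.07), 1e-4)
  expect_lt(abs(ft$y - 0.93), 1e-4)
  expect_lt(abs(ft$wx - psf$wx(0.15)), 1e-4)
  expect_lt(abs(ft$wy - psf$wy(0.15)), 1e-4)
  expect_equal(ft$amplitude, 5000, tolerance = 1e-3)
  expect_error(fit_spot(matrix(0, 15, 15)), "no structure")
})

test_that("lateral precision with 5000 photons beats 15 nm and scales as 1/sqrt(N)", {
  em <- data.frame(frame = 1, x = 1.03, y = 1.01, z = 0)
  err <- function(photons, seeds) {
    vapply(seeds, function(s) {
      st <- render_frames(em, psf, c(21, 21), photons = photons,
                          background = 10, read_noise = 1, seed = s)
      ft <- fit_spot(st[, , 1], pixel_size = 0.1)
      ft$x - em$x
    }, numeric(1))
  }
  e5k <- err(5000, 1:30)
  expect_lt(sd(e5k), 0.015)
  e50 <- err(50000, 1:30)
  ratio <- sd(e5k) / sd(e50)
  expect_gt(ratio, sqrt(10) * 0.5)
  expect_lt(ratio, sqrt(10) * 2)
})

test_that("z calibration round-trips the generating defocus curves", {
  expect_equal(analytic_cal$crossing_width, psf$wx(0), tolerance = 1e-3)
  zs <- seq(-0.35, 0.35, by = 0.05)
  expect_equal(analytic_cal$wx_fun(zs), psf$wx(zs), tolerance = 1e-3)
  expect_equal(analytic_cal$wy_fun(zs), psf$wy(zs), tolerance = 1e-3)

  # mirrored stack (z -> -z, widths swapped) gives a sign-flipped lookup
  zg <- seq(-0.4, 0.4, by = 0.02)
  mirrored <- build_z_calibration(
    data.frame(z = zg, wx = psf$wy(zg), wy = psf$wx(zg)))
  z1 <- z_from_widths(psf$wx(0.2), psf$wy(0.2), analytic_cal)$z
  z2 <- z_from_widths(psf$wx(0.2), psf$wy(0.2), mirrored)$z
  expect_equal(z1, -z2, tolerance = 2e-3)

  expect_error(build_z_calibration(array(0, c(5, 5, 1)), z_positions = 0),
               "single-plane")
  flat <- data.frame(z = zg, wx = 0.13, wy = 0.15)
  expect_error(build_z_calibration(flat), "no wx/wy crossing")
})

test_that("z calibration can be built from a rendered bead stack", {
  zs <- seq(-0.4, 0.4, by = 0.05)
  em <- data.frame(frame = seq_along(zs), x = 1.6, y = 1.6, z = zs)
  st <- render_frames(em, psf, c(32, 32), photons = 20000, background = 5,
                      read_noise = 1, seed = 11)
  cal <- build_z_calibration(st, z_positions = zs, pixel_size = 0.1)
  zt <- seq(-0.3, 0.3, by = 0.1)
  expect_equal(cal$wx_fun(zt), psf$wx(zt), tolerance = 0.02)
  expect_equal(cal$wy_fun(zt), psf$wy(zt), tolerance = 0.02)
})

test_that("width-pair z lookup is exact on the curve and antisymmetric", {
  w0 <- analytic_cal$crossing_width
  z0 <- z_from_widths(w0, w0, analytic_cal)
  expect_lt(abs(z0$z), 1e-3)
  zz <- z_from_widths(psf$wx(0.2), psf$wy(0.2), analytic_cal)
  expect_equal(zz$z, 0.2, tolerance = 1e-3)
  expect_true(zz$valid)
  # swapping wx and wy negates z
  sw <- z_from_widths(psf$wy(0.2), psf$wx(0.2), analytic_cal)
  expect_equal(sw$z, -0.2, tolerance = 1e-3)
  expect_error(z_from_widths(0.15, 0.15, NULL), "calibration")
})

test_that("render -> localize -> z recovers ground truth within QD-like precision", {
  em <- data.frame(frame = 1, x = 1.58, y = 1.62, z = 0.12)
  errs <- vapply(1:25, function(s) {
    st <- render_frames(em, psf, c(32, 32), photons = 5000, background = 10,
                        read_noise = 1, seed = s)
    l <- localize_frames(st, 60, calibration = analytic_cal)
    c(l$x - em$x, l$y - em$y, l$z - em$z)
  }, numeric(3))
  rms <- sqrt(rowMeans(errs^2))
  expect_lt(rms[1], 0.010)
  expect_lt(rms[2], 0.010)
  expect_lt(rms[3], 0.018)
})
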