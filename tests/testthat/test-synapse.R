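test_that("density clustering finds generator clusters and ignores sparse background", {
  sc <- make_scene(1, c(8, 8, 1), seed = 1)
  # uniform sparse background below the density threshold: no clusters
  set.seed(2)
  bg <- data.frame(x = runif(300, 0, 8), y = runif(300, 0, 8),
                   z = runif(300, 0.3, 0.7))
  cl <- cluster_palm(bg, 0.1, 20)
  expect_equal(nrow(cl$clusters), 0)

  # one 500-point cluster, sigma 50 nm, no background
  tab <- simulate_homer_palm(sc, 500, sigma_cluster = 0.05,
                             background_density = 0, seed = 3)
  cl <- cluster_palm(tab, 0.1, 20)
  expect_equal(nrow(cl$clusters), 1)
  err <- sqrt(sum((unlist(cl$clusters[1, c("x", "y")]) -
                     sc$psd_centers[1, 1:2])^2))
  expect_lt(err, 0.010)
  # center equals the member centroid
  mem <- tab[cl$assignment == 1, ]
  expect_equal(cl$clusters$x, mean(mem$x), tolerance = 1e-12)

  # two clusters 2 um apart resolve into two correctly paired clusters
  sc2 <- make_scene(2, c(10, 10, 1), min_spacing = 2, seed = 4)
  tab2 <- simulate_homer_palm(sc2, 400, 0.05, 0, seed = 5)
  cl2 <- cluster_palm(tab2, 0.1, 20)
  expect_equal(nrow(cl2$clusters), 2)
  d <- as.matrix(dist(rbind(as.matrix(cl2$clusters[, c("x", "y", "z")]),
                            sc2$psd_centers)))[1:2, 3:4]
  expect_true(all(apply(d, 1, min) < 0.02))
})

test_that("core-point rule matches brute-force neighbor counting", {
  set.seed(6)
  pos <- cbind(c(rnorm(60, 0, 0.05), runif(20, -1, 1)),
               c(rnorm(60, 0, 0.05), runif(20, -1, 1)),
               0)
  counts <- brute_neighbor_counts(pos, 0.1)
  cl <- cluster_palm(data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3]),
                     0.1, 20)
  # every point with >= 20 neighbors must be in a cluster
  expect_true(all(cl$assignment[counts >= 20] > 0))
  # points with no dense neighborhood anywhere near remain background
  expect_true(all(cl$assignment[counts <= 2] == 0))
})

test_that("synaptic rule: distance gates behave at the stated constants", {
  centers <- data.frame(x = 0, y = 0, z = 0)
  at_center <- data.frame(track = 1, frame = 1:20, x = 0, y = 0, z = 0)
  out <- classify_synaptic(at_center, centers)
  expect_true(out$synaptic)
  expect_equal(out$mean_distance, 0)

  # mean distance 0.6 um -> non-synaptic under the 0.55 um rule
  ring <- data.frame(track = 1, frame = 1:20, x = 0.6, y = 0, z = 0)
  expect_false(classify_synaptic(ring, centers)$synaptic)

  # no cluster within the 2 um candidate radius -> never synaptic
  far <- data.frame(track = 1, frame = 1:20, x = 2.5, y = 0, z = 0)
  expect_false(classify_synaptic(far, centers)$synaptic)

  # no clusters at all -> non-synaptic
  none <- classify_synaptic(at_center,
                            data.frame(x = numeric(), y = numeric(),
                                       z = numeric()))
  expect_false(none$synaptic)
})

test_that("synaptic and non-synaptic counts partition the track set", {
  sc <- make_scene(5, c(15, 15, 1), seed = 7)
  pop <- simulate_population("sqd_sa", sc, 150,
                             acquisition_params(n_frames = 60), seed = 8)
  out <- classify_synaptic(pop, data.frame(sc$psd_centers))
  expect_equal(nrow(out), 150)
  expect_equal(sum(out$synaptic) + sum(!out$synaptic), 150)
})

test_that("ground-truth synaptic labels are recovered with >= 95% balanced accuracy", {
  sc <- make_scene(8, c(20, 20, 1), min_spacing = 2, seed = 9)
  pop <- simulate_population("sqd_sa", sc, 150,
                             acquisition_params(n_frames = 600), seed = 10)
  palm <- simulate_homer_palm(sc, 400, 0.06, 2, seed = 11)
  cl <- cluster_palm(palm)
  pred <- classify_synaptic(pop, cl)
  truth <- pop$truth$synaptic
  sens <- mean(pred$synaptic[truth])
  spec <- mean(!pred$synaptic[!truth])
  expect_gte((sens + spec) / 2, 0.95)
})

test_that("distance fractions are monotone in radius and exact at the center", {
  centers <- data.frame(x = c(0, 5), y = 0, z = 0)
  tracks <- data.frame(track = rep(1:3, each = 5), frame = rep(1:5, 3),
                       x = rep(c(0, 0.3, 5.8), each = 5), y = 0, z = 0)
  df <- distance_fractions(tracks, centers, radii = c(0.5, 1.0))
  expect_equal(unname(df$fractions["within_0.5um"]), 2 / 3)
  expect_equal(unname(df$fractions["within_1um"]), 1)
  expect_true(all(diff(df$fractions) >= 0))

  all_center <- data.frame(track = rep(1:4, each = 3), frame = rep(1:3, 4),
                           x = 0, y = 0, z = 0)
  df0 <- distance_fractions(all_center, centers)
  expect_true(all(df0$fractions == 1))
  expect_error(distance_fractions(tracks,
                                  data.frame(x = numeric(), y = numeric())),
               "empty cluster")
})

test_that("rigid epoch alignment: identity, known transform, and 3-point oracle", {
  set.seed(12)
  a <- matrix(rnorm(45, sd = 0.08), 15, 3)
  id <- align_epochs(a, a)
  expect_equal(sqrt(sum(id$translation^2)), 0, tolerance = 1e-9)
  expect_equal(unname(id$rotation_deg), c(0, 0), tolerance = 1e-7)
  expect_equal(id$overlap, 1)

  # 19 deg in-plane rotation + 100 nm shift, the epoch-drift scale
  th <- 19 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b <- a %*% t(Rz)
  b <- sweep(b, 2, -c(0.1, 0, 0))
  al <- align_epochs(a, b)
  expect_equal(unname(al$rotation_deg["theta_z"]), 19, tolerance = 1e-6)
  expect_equal(sqrt(sum(al$translation^2)), 0.1, tolerance = 1e-6)
  expect_lt(al$rms, 1e-9)

  # second-axis rotation is recovered too
  ph <- 10 * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3, 3)
  b2 <- a %*% t(Rx %*% Rz)
  al2 <- align_epochs(a, b2)
  expect_equal(unname(al2$rotation_deg), c(19, 10), tolerance = 1e-5)

  # 3-point sets against the dense rotation-grid oracle
  a3 <- matrix(c(0, 0, 0, 0.2, 0, 0, 0, 0.15, 0), 3, 3, byrow = TRUE)
  th3 <- -37 * pi / 180
  R3 <- matrix(c(cos(th3), sin(th3), 0, -sin(th3), cos(th3), 0, 0, 0, 1),
               3, 3)
  b3 <- sweep(a3 %*% t(R3), 2, -c(0.05, -0.03, 0))
  want <- brute_rigid_2d(a3, b3)
  al3 <- align_epochs(a3, b3)
  expect_equal(unname(al3$rotation_deg["theta_z"]), want$theta_deg,
               tolerance = 0.1)
  expect_lte(al3$rms, want$rms + 1e-9)

  expect_error(align_epochs(a3[1:2, ], b3), ">= 3 points")
  coll <- cbind(1:5, 2 * (1:5), 0)
  expect_error(align_epochs(coll, coll), "collinear")
})

test_that("alignment never increases RMS relative to the identity transform", {
  set.seed(14)
  for (rep in 1:5) {
    a <- matrix(rnorm(30, sd = 0.1), 10, 3)
    b <- a + matrix(rnorm(30, sd = 0.03), 10, 3)
    al <- align_epochs(a, b)
    expect_lte(al$rms, al$rms_identity + 1e-12)
  }
})
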