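# Trajectory generators: unbounded Brownian motion and Brownian motion
# reflected inside a sphere (hard confinement). All batch engines return an
# array [frame, track, axis] of noise-free positions; localization noise is
# appended afterwards so ground truth stays available.

# radial reflection at the sphere boundary; repeated for the (rare) case of
# steps larger than the sphere
reflect_into_sphere <- function(pos, radius) {
  for (it in 1:6) {
    rho <- sqrt(rowSums(pos^2))
    out <- which(rho > radius)
    if (!length(out)) return(pos)
    fac <- abs(2 * radius[out] - rho[out]) / rho[out]
    pos[out, ] <- pos[out, , drop = FALSE] * fac
  }
  rho <- sqrt(rowSums(pos^2))
  bad <- rho > radius
  if (any(bad)) {
    pos[bad, ] <- pos[bad, , drop = FALSE] * (0.999 * radius[bad] / rho[bad])
  }
  pos
}

sim_confined_batch <- function(n_tracks, n_frames, dt, d_coeff, radius,
                               start = c("stationary", "center")) {
  start <- match.arg(start)
  stopifnot(length(d_coeff) == n_tracks, length(radius) == n_tracks)
  sig <- sqrt(2 * d_coeff * dt)
  if (start == "stationary") {
    # stationary law of reflected Brownian motion is uniform in the sphere
    u <- matrix(rnorm(3 * n_tracks), n_tracks, 3)
    u <- u / sqrt(rowSums(u^2))
    pos <- u * (radius * runif(n_tracks)^(1 / 3))
  } else {
    pos <- matrix(0, n_tracks, 3)
  }
  out <- array(NA_real_, c(n_frames, n_tracks, 3))
  out[1, , ] <- pos
  if (n_frames > 1) {
    for (f in 2:n_frames) {
      pos <- pos + matrix(rnorm(3 * n_tracks), n_tracks, 3) * sig
      pos <- reflect_into_sphere(pos, radius)
      out[f, , ] <- pos
    }
  }
  out
}

sim_free_batch <- function(n_tracks, n_frames, dt, d_coeff) {
  stopifnot(length(d_coeff) == n_tracks)
  sig <- sqrt(2 * d_coeff * dt)
  out <- array(NA_real_, c(n_frames, n_tracks, 3))
  for (ax in 1:3) {
    steps <- matrix(rnorm((n_frames - 1) * n_tracks), n_frames - 1, n_tracks)
    steps <- sweep(steps, 2, sig, `*`)
    out[, , ax] <- rbind(0, apply(steps, 2, cumsum))
  }
  out
}

shift_by_centers <- function(arr, centers) {
  n_frames <- dim(arr)[1]
  n_tracks <- dim(arr)[2]
  for (ax in 1:3) {
    arr[, , ax] <- arr[, , ax] +
      matrix(centers[, ax], n_frames, n_tracks, byrow = TRUE)
  }
  arr
}

add_localization_noise <- function(arr, noise) {
  n <- dim(arr)[1] * dim(arr)[2]
  for (ax in 1:3) {
    if (noise[ax] > 0) {
      arr[, , ax] <- arr[, , ax] + rnorm(n, sd = noise[ax])
    }
  }
  arr
}

#' Simulate a single receptor trajectory
#'
#' Generates one 3D track, either free (unbounded Brownian motion) or
#' confined (Brownian motion reflected inside a sphere of the given radius,
#' the hard-wall model of a receptor held in a nanodomain). Per-axis
#' Gaussian localization noise from `acq` is appended to the true positions.
#'
#' @param kind `"free"` or `"confined"`.
#' @param d_coeff diffusion coefficient in µm²/s (>= 0).
#' @param center 3-vector, µm: start position (free) or sphere center
#'   (confined).
#' @param radius confinement radius in µm (confined only; default 0.1, a
#'   ~200 nm nanodomain).
#' @param acq [acquisition_params()] object.
#' @param seed integer seed.
#' @return A `data.frame` (class `spt_trajectory`) with columns `frame`,
#'   `x`, `y`, `z` (µm); attributes `frame_interval` (s) and
#'   `true_positions` (noise-free n x 3 matrix).
#' @examples
#' tr <- simulate_trajectory("confined", 0.003, radius = 0.1,
#'                           acq = acquisition_params(n_frames = 50), seed = 1)
#' max(dist(attr(tr, "true_positions"))) <= 0.2
#' @export
simulate_trajectory <- function(kind = c("free", "confined"),
                                d_coeff,
                                center = c(0, 0, 0),
                                radius = 0.1,
                                acq = acquisition_params(),
                                seed = 1) {
  kind <- match.arg(kind)
  stopifnot(d_coeff >= 0, length(center) == 3, acq$n_frames >= 2)
  if (kind == "confined") stopifnot(radius > 0)
  with_seed(derive_seed(seed, paste0("trajectory-", kind)), {
    arr <- if (kind == "free") {
      sim_free_batch(1L, acq$n_frames, acq$frame_interval, d_coeff)
    } else {
      sim_confined_batch(1L, acq$n_frames, acq$frame_interval, d_coeff,
                         radius, start = "stationary")
    }
    arr <- shift_by_centers(arr, matrix(center, 1, 3))
    true_pos <- cbind(arr[, 1, 1], arr[, 1, 2], arr[, 1, 3])
    arr <- add_localization_noise(arr, acq$localization_noise)
    out <- data.frame(frame = seq_len(acq$n_frames),
                      x = arr[, 1, 1], y = arr[, 1, 2], z = arr[, 1, 3])
    attr(out, "frame_interval") <- acq$frame_interval
    attr(out, "true_positions") <- true_pos
    class(out) <- c("spt_trajectory", "data.frame")
    out
  })
}

#' Simulate a population of trajectories from a probe preset
#'
#' Draws `n_tracks` tracks from the three subpopulations a preset encodes:
#' fast/free extrasynaptic tracks (Brownian motion reflected in a sphere
#' whose diameter is drawn from the preset's fast trajectory-range
#' distribution), confined synaptic tracks attached to scene nanodomain
#' centers, and confined extrasynaptic tracks. Each track's diffusion
#' coefficient is drawn log-normally around the preset's population mean.
#' Extrasynaptic track centers are placed at a preset-specific distance from
#' a randomly chosen PSD. Ground-truth labels are retained per track.
#'
#' @param preset an [population_preset()] object or a preset name.
#' @param scene an [make_scene()] scene.
#' @param n_tracks number of tracks.
#' @param acq [acquisition_params()] object.
#' @param seed integer seed.
#' @return A list of class `spt_population`: `tracks`, a long `data.frame`
#'   (`track`, `frame`, `x`, `y`, `z`); `truth`, one row per track with
#'   `track`, `kind` ("free"/"confined"), `synaptic` (logical), `d_coeff`,
#'   `radius`, `center_x/y/z`, `psd` (index or `NA`); `frame_interval`.
#' @examples
#' sc <- make_scene(2, field_size = c(10, 10, 1), seed = 1)
#' pop <- simulate_population("sqd_sa", sc, n_tracks = 20,
#'                            acq = acquisition_params(n_frames = 30), seed = 1)
#' table(pop$truth$kind)
#' @export
simulate_population <- function(preset, scene, n_tracks,
                                acq = acquisition_params(), seed = 1) {
  if (is.character(preset)) preset <- population_preset(preset)
  stopifnot(inherits(preset, "spt_preset"), inherits(scene, "spt_scene"),
            n_tracks >= 1)
  with_seed(derive_seed(seed, paste0("population-", preset$name)), {
    u <- runif(n_tracks)
    kind <- ifelse(u < preset$fraction_fast, "free", "confined")
    synaptic <- u >= preset$fraction_fast &
      u < preset$fraction_fast + preset$synaptic_fraction

    is_fast <- kind == "free"
    d <- numeric(n_tracks)
    d[is_fast] <- 10^rnorm(sum(is_fast), preset$d_fast_log10, preset$sd_fast)
    d[!is_fast] <- 10^rnorm(sum(!is_fast), preset$d_slow_log10, preset$sd_slow)

    rng <- numeric(n_tracks)
    rng[is_fast] <- pmax(rnorm(sum(is_fast), preset$range_fast_um,
                               preset$range_fast_sd), 0.4)
    rng[!is_fast] <- pmax(rnorm(sum(!is_fast), preset$range_slow_um,
                                preset$range_slow_sd), 0.12)
    radius <- rng / 2

    centers <- matrix(NA_real_, n_tracks, 3)
    psd <- rep(NA_integer_, n_tracks)
    # synaptic confined tracks: a nanodomain center
    n_syn <- sum(synaptic)
    if (n_syn > 0) {
      nd_idx <- sample.int(nrow(scene$nanodomains), n_syn, replace = TRUE)
      centers[synaptic, ] <- as.matrix(scene$nanodomains[nd_idx, c("x", "y", "z")])
      psd[synaptic] <- scene$nanodomains$psd[nd_idx]
    }
    # extrasynaptic tracks (fast or confined): offset from a random PSD
    extra <- !synaptic
    n_ext <- sum(extra)
    if (n_ext > 0) {
      psd_idx <- sample.int(nrow(scene$psd_centers), n_ext, replace = TRUE)
      dist_rng <- preset$extrasyn_dist_um
      dd <- runif(n_ext, dist_rng[1], dist_rng[2])
      dir <- matrix(rnorm(3 * n_ext), n_ext, 3)
      dir[, 3] <- dir[, 3] * 0.2   # offsets stay close to the membrane plane
      dir <- dir / sqrt(rowSums(dir^2))
      centers[extra, ] <- scene$psd_centers[psd_idx, , drop = FALSE] + dir * dd
    }

    arr <- array(NA_real_, c(acq$n_frames, n_tracks, 3))
    if (any(is_fast)) {
      arr[, is_fast, ] <- sim_confined_batch(
        sum(is_fast), acq$n_frames, acq$frame_interval,
        d[is_fast], radius[is_fast], start = "stationary")
    }
    if (any(!is_fast)) {
      arr[, !is_fast, ] <- sim_confined_batch(
        sum(!is_fast), acq$n_frames, acq$frame_interval,
        d[!is_fast], radius[!is_fast], start = "stationary")
    }
    arr <- shift_by_centers(arr, centers)
    arr <- add_localization_noise(arr, acq$localization_noise)

    tracks <- data.frame(
      track = rep(seq_len(n_tracks), each = acq$n_frames),
      frame = rep(seq_len(acq$n_frames), n_tracks),
      x = as.vector(arr[, , 1]),
      y = as.vector(arr[, , 2]),
      z = as.vector(arr[, , 3])
    )
    truth <- data.frame(
      track = seq_len(n_tracks), kind = kind, synaptic = synaptic,
      d_coeff = d, radius = radius,
      center_x = centers[, 1], center_y = centers[, 2], center_z = centers[, 3],
      psd = psd
    )
    structure(
      list(tracks = tracks, truth = truth,
           frame_interval = acq$frame_interval, preset = preset$name),
      class = "spt_population"
    )
  })
}

#' @export
print.spt_population <- function(x, ...) {
  cat("Simulated population (preset ", x$preset, "): ",
      nrow(x$truth), " tracks, ",
      sum(x$truth$kind == "free"), " free / ",
      sum(x$truth$kind == "confined"), " confined, ",
      sum(x$truth$synaptic), " synaptic\n", sep = "")
  invisible(x)
}
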