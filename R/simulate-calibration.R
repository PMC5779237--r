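# Generators for the calibration inputs of the pipeline: PALM tables of PSD
# marker localizations, fiducial drift traces, and paired two-channel
# nanohole-grid localizations carrying a smooth chromatic distortion.

#' Simulate a Homer1c PALM localization table
#'
#' Draws localizations around every PSD center of a scene (isotropic
#' Gaussian scatter of sd `sigma_cluster`, compressed in z) plus a uniform
#' background at the stated density, emulating a PALM acquisition of a
#' photoactivatable PSD marker collected over thousands of frames.
#'
#' @param scene an [make_scene()] scene (may have zero PSDs via
#'   `psd_centers` subsetting).
#' @param locs_per_cluster localizations per PSD (>= 1).
#' @param sigma_cluster lateral cluster sd in µm (default 0.06, a PSD-sized
#'   spot).
#' @param background_density background localizations per µm² (>= 0).
#' @param n_frames number of camera frames localizations are spread over.
#' @param seed integer seed.
#' @return `data.frame` with `frame`, `x`, `y`, `z` (µm), `cluster`
#'   (ground-truth PSD index, 0 for background).
#' @export
simulate_homer_palm <- function(scene, locs_per_cluster = 400,
                                sigma_cluster = 0.06,
                                background_density = 2,
                                n_frames = 5000, seed = 1) {
  stopifnot(inherits(scene, "spt_scene"), locs_per_cluster >= 1)
  if (background_density < 0) stop("background_density must be >= 0")
  with_seed(derive_seed(seed, "homer-palm"), {
    n_psd <- nrow(scene$psd_centers)
    parts <- list()
    if (n_psd > 0) {
      for (i in seq_len(n_psd)) {
        ctr <- scene$psd_centers[i, ]
        parts[[i]] <- data.frame(
          x = rnorm(locs_per_cluster, ctr[1], sigma_cluster),
          y = rnorm(locs_per_cluster, ctr[2], sigma_cluster),
          z = rnorm(locs_per_cluster, ctr[3], 0.6 * sigma_cluster),
          cluster = i
        )
      }
    }
    n_bg <- rpois(1, background_density * scene$field_size[1] *
                    scene$field_size[2])
    if (n_bg > 0) {
      parts[[length(parts) + 1]] <- data.frame(
        x = runif(n_bg, 0, scene$field_size[1]),
        y = runif(n_bg, 0, scene$field_size[2]),
        z = runif(n_bg, 0.35 * scene$field_size[3],
                  0.65 * scene$field_size[3]),
        cluster = 0L
      )
    }
    out <- if (length(parts)) do.call(rbind, parts) else
      data.frame(x = numeric(), y = numeric(), z = numeric(),
                 cluster = integer())
    out$frame <- if (nrow(out)) sample.int(n_frames, nrow(out), replace = TRUE)
      else integer()
    rownames(out) <- NULL
    out[, c("frame", "x", "y", "z", "cluster")]
  })
}

#' Simulate fiducial marker traces under stage drift
#'
#' Fiducials sit on a uniform grid (patterned coverslip). Each per-frame
#' localization equals the fixed grid position plus the common drift at that
#' frame plus independent Gaussian localization noise.
#'
#' @param drift either a function of time (seconds) returning a 3-vector in
#'   µm, or an `n_frames` x 3 matrix of per-frame drift (µm).
#' @param n_fiducials number of fiducials (>= 1; laid out on a near-square
#'   grid).
#' @param noise localization noise sd in µm, scalar (isotropic) or
#'   length-3.
#' @param acq [acquisition_params()] object.
#' @param grid_pitch fiducial grid pitch in µm.
#' @param seed integer seed.
#' @return A list of class `spt_fiducials`: `table` (`data.frame` with
#'   `frame`, `fiducial`, `x`, `y`, `z`), `true_drift` (`n_frames` x 3
#'   matrix, µm), `grid` (fiducial positions).
#' @export
simulate_fiducials <- function(drift, n_fiducials = 25, noise = 0.005,
                               acq = acquisition_params(),
                               grid_pitch = 4, seed = 1) {
  stopifnot(n_fiducials >= 1)
  if (length(noise) == 1) noise <- rep(noise, 3)
  stopifnot(all(noise >= 0))
  n_frames <- acq$n_frames
  times <- (seq_len(n_frames) - 1) * acq$frame_interval
  drift_mat <- if (is.function(drift)) {
    t(vapply(times, drift, numeric(3)))
  } else {
    stopifnot(is.matrix(drift), nrow(drift) == n_frames, ncol(drift) == 3)
    drift
  }
  with_seed(derive_seed(seed, "fiducials"), {
    side <- ceiling(sqrt(n_fiducials))
    gx <- ((seq_len(n_fiducials) - 1) %% side) * grid_pitch
    gy <- ((seq_len(n_fiducials) - 1) %/% side) * grid_pitch
    grid <- cbind(x = gx, y = gy, z = 0)
    tab <- data.frame(
      frame = rep(seq_len(n_frames), n_fiducials),
      fiducial = rep(seq_len(n_fiducials), each = n_frames),
      x = rep(grid[, 1], each = n_frames) + rep(drift_mat[, 1], n_fiducials),
      y = rep(grid[, 2], each = n_frames) + rep(drift_mat[, 2], n_fiducials),
      z = rep(grid[, 3], each = n_frames) + rep(drift_mat[, 3], n_fiducials)
    )
    n <- nrow(tab)
    tab$x <- tab$x + rnorm(n, sd = noise[1])
    tab$y <- tab$y + rnorm(n, sd = noise[2])
    tab$z <- tab$z + rnorm(n, sd = noise[3])
    structure(list(table = tab, true_drift = drift_mat, grid = grid),
              class = "spt_fiducials")
  })
}

#' Smooth chromatic distortion field
#'
#' A low-order (quadratic) smooth displacement field between two color
#' channels. Coefficients are drawn at random and rescaled so the RMS
#' displacement magnitude over the field equals `amplitude` (default
#' 0.08 µm, the ~80 nm inter-channel offset typical of an achromat-corrected
#' objective). An optional linear z-dependence models the axial growth of
#' the aberration away from focus.
#'
#' @param amplitude RMS displacement magnitude in µm.
#' @param extent field half-extent in µm used for normalization.
#' @param z_gradient additional displacement per µm of defocus (µm/µm,
#'   applied along a fixed direction).
#' @param seed integer seed for the random coefficients.
#' @return A function `f(xy, z = 0)` mapping an n x 2 matrix of positions
#'   (µm) to an n x 2 matrix of displacements (µm), with class
#'   `spt_distortion`.
#' @export
distortion_field <- function(amplitude = 0.08, extent = 30,
                             z_gradient = 0.005, seed = 1) {
  stopifnot(amplitude >= 0, extent > 0)
  cf <- with_seed(derive_seed(seed, "distortion"), {
    matrix(rnorm(12), 2, 6)  # per-axis: 1, x, y, x^2, xy, y^2 (normalized)
  })
  # normalize RMS magnitude on a reference grid
  g <- seq(-1, 1, length.out = 15)
  gg <- as.matrix(expand.grid(g, g))
  basis <- cbind(1, gg[, 1], gg[, 2], gg[, 1]^2, gg[, 1] * gg[, 2], gg[, 2]^2)
  disp <- basis %*% t(cf)
  rms <- sqrt(mean(rowSums(disp^2)))
  scale <- if (rms > 0) amplitude / rms else 0
  cf <- cf * scale
  zdir <- c(1, 0.4) / sqrt(1.16)
  f <- function(xy, z = 0) {
    xy <- as.matrix(xy)
    xn <- xy[, 1] / extent
    yn <- xy[, 2] / extent
    b <- cbind(1, xn, yn, xn^2, xn * yn, yn^2)
    d <- b %*% t(cf)
    if (any(z != 0)) {
      d <- d + outer(rep_len(z, nrow(xy)) * z_gradient, zdir)
    }
    d
  }
  structure(f, class = c("spt_distortion", "function"),
            amplitude = amplitude, z_gradient = z_gradient)
}

#' Simulate a paired two-channel nanohole grid
#'
#' Nanoholes sit on a square grid of the given pitch. Channel-1 positions
#' are the hole positions plus localization noise; channel-2 positions are
#' additionally displaced by the chromatic distortion field. Ground-truth
#' correspondence is retained (row i of both tables is the same hole).
#'
#' @param pitch grid pitch in µm (default 1.5).
#' @param field a [distortion_field()] (or any function of an n x 2 matrix
#'   returning n x 2 displacements in µm).
#' @param loc_noise 2D RMS localization error per hole per channel, in µm
#'   (per-axis sd is `loc_noise / sqrt(2)`). Default 0.001 (1 nm).
#' @param grid_extent integer 2-vector: number of holes per axis.
#' @param z defocus (µm) at which channel-2 positions are produced.
#' @param seed integer seed.
#' @return A list of class `spt_nanoholes`: `ch1`, `ch2` (`data.frame`s with
#'   `hole`, `x`, `y`), `true_positions`, `true_displacement`.
#' @export
simulate_nanohole_pair <- function(pitch = 1.5,
                                   field = distortion_field(),
                                   loc_noise = 0.001,
                                   grid_extent = c(40, 40),
                                   z = 0, seed = 1) {
  stopifnot(pitch > 0, all(grid_extent >= 1))
  if (prod(grid_extent) < 1) stop("empty grid")
  with_seed(derive_seed(seed, "nanoholes"), {
    gx <- (seq_len(grid_extent[1]) - 1) * pitch
    gy <- (seq_len(grid_extent[2]) - 1) * pitch
    pos <- as.matrix(expand.grid(x = gx, y = gy))
    # center the grid so the field is evaluated symmetrically
    pos <- sweep(pos, 2, colMeans(pos))
    n <- nrow(pos)
    disp <- field(pos, z = z)
    sig <- loc_noise / sqrt(2)
    ch1 <- pos + matrix(rnorm(2 * n, sd = sig), n, 2)
    ch2 <- pos + disp + matrix(rnorm(2 * n, sd = sig), n, 2)
    structure(
      list(
        ch1 = data.frame(hole = seq_len(n), x = ch1[, 1], y = ch1[, 2]),
        ch2 = data.frame(hole = seq_len(n), x = ch2[, 1], y = ch2[, 2]),
        true_positions = pos, true_displacement = disp
      ),
      class = "spt_nanoholes"
    )
  })
}
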