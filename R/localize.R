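# Spot detection, elliptical-Gaussian fitting, and width-pair -> z lookup.

#' Detect candidate spots in a frame
#'
#' Local maxima above an intensity threshold, with non-maximum suppression:
#' a pixel is kept only if it is the maximum of its
#' `(2 * min_separation + 1)^2` neighborhood.
#'
#' @param frame 2D numeric matrix of counts.
#' @param intensity_threshold minimum peak value.
#' @param min_separation suppression radius in pixels.
#' @param pixel_size pixel size in µm (for the returned µm coordinates).
#' @return `data.frame` with `row`, `col` (pixels), `x`, `y` (µm, pixel
#'   centers), `value`. Zero rows when nothing exceeds the threshold.
#' @export
detect_spots <- function(frame, intensity_threshold, min_separation = 2,
                         pixel_size = 0.1) {
  if (!is.matrix(frame) || length(frame) == 0) stop("empty frame")
  nr <- nrow(frame); nc <- ncol(frame)
  s <- as.integer(min_separation)
  cand <- which(frame > intensity_threshold, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    r0 <- max(1, r - s); r1 <- min(nr, r + s)
    c0 <- max(1, c - s); c1 <- min(nc, c + s)
    nb <- frame[r0:r1, c0:c1]
    keep[i] <- frame[r, c] >= max(nb) &&
      which.max(nb) == (r - r0 + 1) + (c - c0) * (r1 - r0 + 1)
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(row = cand[, 1], col = cand[, 2],
             x = (cand[, 2] - 0.5) * pixel_size,
             y = (cand[, 1] - 0.5) * pixel_size,
             value = frame[cand])
}

#' Fit an elliptical Gaussian to an image patch
#'
#' Least-squares fit of a pixel-integrated elliptical 2D Gaussian
#' (amplitude, center, per-axis sigma, constant background) by
#' Levenberg-Marquardt. Non-convergent fits are flagged, never silently
#' kept.
#'
#' @param patch 2D numeric matrix containing one spot.
#' @param init optional `c(row, col)` initial center (pixels); defaults to
#'   the patch maximum.
#' @param pixel_size pixel size in µm.
#' @param w_init initial sigma guess in µm.
#' @return An object of class `spt_spotfit`: `x`, `y` (µm, relative to the
#'   patch origin), `wx`, `wy` (Gaussian sigma, µm), `amplitude` (photons),
#'   `background` (photons/pixel), `converged`, `fit_residual` (RMS
#'   residual / amplitude).
#' @export
fit_spot <- function(patch, init = NULL, pixel_size = 0.1, w_init = 0.15) {
  if (!is.matrix(patch) || length(patch) == 0) stop("empty patch")
  if (all(patch == patch[1])) stop("patch has no structure to fit")
  nr <- nrow(patch); nc <- ncol(patch)
  if (is.null(init)) init <- which(patch == max(patch), arr.ind = TRUE)[1, ]
  bg0 <- stats::median(patch)
  a0 <- max(sum(patch - bg0), max(patch) - bg0)
  xe <- (0:nc) * pixel_size
  ye <- (0:nr) * pixel_size
  model <- function(p) {
    # p: log-amplitude, x0, y0, log wx, log wy, background
    px <- diff(stats::pnorm(xe, p[2], exp(p[4])))
    py <- diff(stats::pnorm(ye, p[3], exp(p[5])))
    exp(p[1]) * outer(py, px) + p[6]
  }
  p0 <- c(log(a0), (init[2] - 0.5) * pixel_size, (init[1] - 0.5) * pixel_size,
          log(w_init), log(w_init), bg0)
  fit <- minpack.lm::nls.lm(
    par = p0,
    fn = function(p) as.vector(model(p) - patch),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- unname(fit$par)
  converged <- fit$info %in% 1:4
  structure(
    list(
      x = p[2], y = p[3], wx = exp(p[4]), wy = exp(p[5]),
      amplitude = exp(p[1]), background = p[6],
      converged = converged,
      fit_residual = sqrt(mean(fit$fvec^2)) / exp(p[1])
    ),
    class = "spt_spotfit"
  )
}

#' Localize emitters in an image stack
#'
#' Convenience wrapper: detect candidates per frame, fit each in a square
#' patch, convert widths to z when a calibration is supplied. Non-converged
#' fits are dropped and counted.
#'
#' @param stack 3D array `[row, col, frame]`.
#' @param intensity_threshold,min_separation passed to [detect_spots()].
#' @param halfwidth patch half-width in pixels.
#' @param pixel_size pixel size in µm.
#' @param calibration optional [build_z_calibration()] curve.
#' @return `data.frame` with `frame`, `x`, `y` (µm), `wx`, `wy`,
#'   `intensity`, `background`, and (with calibration) `z`, `z_valid`;
#'   attribute `n_dropped` counts non-converged fits.
#' @export
localize_frames <- function(stack, intensity_threshold, min_separation = 2,
                            halfwidth = 7, pixel_size = 0.1,
                            calibration = NULL) {
  stopifnot(length(dim(stack)) == 3)
  rows <- list()
  dropped <- 0L
  for (f in seq_len(dim(stack)[3])) {
    frame <- stack[, , f]
    cand <- detect_spots(frame, intensity_threshold, min_separation,
                         pixel_size)
    for (i in seq_len(nrow(cand))) {
      r <- cand$row[i]; c <- cand$col[i]
      r0 <- max(1, r - halfwidth); r1 <- min(nrow(frame), r + halfwidth)
      c0 <- max(1, c - halfwidth); c1 <- min(ncol(frame), c + halfwidth)
      ft <- try(fit_spot(frame[r0:r1, c0:c1],
                         init = c(r - r0 + 1, c - c0 + 1),
                         pixel_size = pixel_size), silent = TRUE)
      if (inherits(ft, "try-error") || !ft$converged) {
        dropped <- dropped + 1L
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        frame = f,
        x = ft$x + (c0 - 1) * pixel_size,
        y = ft$y + (r0 - 1) * pixel_size,
        wx = ft$wx, wy = ft$wy,
        intensity = ft$amplitude, background = ft$background
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(), x = numeric(), y = numeric(),
               wx = numeric(), wy = numeric(), intensity = numeric(),
               background = numeric())
  if (!is.null(calibration) && nrow(out)) {
    zz <- z_from_widths(out$wx, out$wy, calibration)
    out$z <- zz$z
    out$z_valid <- zz$valid
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Build a z calibration curve from a bead defocus series
#'
#' Accepts either a 3D bead stack with one bead per plane at known z steps
#' (planes are localized with [detect_spots()] / [fit_spot()]) or a
#' `data.frame` of per-plane widths (`z`, `wx`, `wy`). Smooth curves are
#' fitted to per-plane median widths; the crossing of wx(z) and wy(z)
#' defines z = 0 and the z grid is shifted accordingly.
#'
#' @param x 3D array `[row, col, plane]` or `data.frame(z, wx, wy)`.
#' @param z_positions plane z positions in µm (stack input only).
#' @param pixel_size pixel size in µm (stack input only).
#' @param intensity_threshold detection threshold (stack input only).
#' @param spar smoothing parameter for the width splines.
#' @return An object of class `spt_zcal`: functions `wx_fun(z)`,
#'   `wy_fun(z)`, the sampled `curve` data.frame, `valid_range` (µm),
#'   `crossing_width` (µm).
#' @export
build_z_calibration <- function(x, z_positions = NULL, pixel_size = 0.1,
                                intensity_threshold = NULL, spar = 0.3) {
  if (is.data.frame(x)) {
    widths <- x[order(x$z), c("z", "wx", "wy")]
  } else {
    stopifnot(length(dim(x)) == 3)
    if (dim(x)[3] < 2) stop("single-plane stack: need a z series")
    stopifnot(length(z_positions) == dim(x)[3])
    if (is.null(intensity_threshold)) {
      intensity_threshold <- stats::median(x) + 5 * stats::mad(x)
    }
    ws <- lapply(seq_len(dim(x)[3]), function(i) {
      frame <- x[, , i]
      cand <- detect_spots(frame, intensity_threshold, 3, pixel_size)
      if (!nrow(cand)) return(NULL)
      cand <- cand[which.max(cand$value), ]
      r <- cand$row; c <- cand$col
      hw <- 8
      r0 <- max(1, r - hw); r1 <- min(nrow(frame), r + hw)
      c0 <- max(1, c - hw); c1 <- min(ncol(frame), c + hw)
      ft <- fit_spot(frame[r0:r1, c0:c1], c(r - r0 + 1, c - c0 + 1),
                     pixel_size)
      if (!ft$converged) return(NULL)
      data.frame(z = z_positions[i], wx = ft$wx, wy = ft$wy)
    })
    widths <- do.call(rbind, ws)
    if (is.null(widths) || nrow(widths) < 4) {
      stop("too few usable calibration planes")
    }
    widths <- widths[order(widths$z), ]
    widths <- stats::aggregate(cbind(wx, wy) ~ z, widths, stats::median)
  }
  if (nrow(widths) < 2) stop("single-plane stack: need a z series")
  sx <- stats::smooth.spline(widths$z, widths$wx, spar = spar)
  sy <- stats::smooth.spline(widths$z, widths$wy, spar = spar)
  wx_fun <- function(z) stats::predict(sx, z)$y
  wy_fun <- function(z) stats::predict(sy, z)$y
  zr <- range(widths$z)
  grid <- seq(zr[1], zr[2], length.out = 2001)
  dif <- wx_fun(grid) - wy_fun(grid)
  sgn <- sign(dif)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(cross)) stop("no wx/wy crossing found in the sampled z range")
  z0 <- stats::uniroot(function(z) wx_fun(z) - wy_fun(z),
                       c(grid[cross[1]], grid[cross[1] + 1]))$root
  curve_df <- data.frame(z = grid - z0, wx = wx_fun(grid), wy = wy_fun(grid))
  structure(
    list(
      wx_fun = function(z) wx_fun(z + z0),
      wy_fun = function(z) wy_fun(z + z0),
      curve = curve_df,
      valid_range = zr - z0,
      crossing_width = wx_fun(z0)
    ),
    class = "spt_zcal"
  )
}

#' @export
print.spt_zcal <- function(x, ...) {
  cat(sprintf(
    "z calibration: valid %.0f..%.0f nm, crossing width %.1f nm (sigma)\n",
    1000 * x$valid_range[1], 1000 * x$valid_range[2],
    1000 * x$crossing_width))
  invisible(x)
}

#' @export
plot.spt_zcal <- function(x, ...) {
  plot(x$curve$z * 1000, x$curve$wx * 1000, type = "l", col = "firebrick",
       xlab = "z (nm)", ylab = "width sigma (nm)",
       ylim = range(c(x$curve$wx, x$curve$wy)) * 1000, ...)
  lines(x$curve$z * 1000, x$curve$wy * 1000, col = "navy")
  legend("top", c("wx", "wy"), col = c("firebrick", "navy"), lty = 1,
         bty = "n")
  invisible(x)
}

#' Convert a width pair to z via a calibration curve
#'
#' For each measured (wx, wy) pair, finds the z minimizing the distance to
#' the calibration curves in (sqrt(wx), sqrt(wy)) space — the square-root
#' metric damps the leverage of the large defocused width — by dense-grid
#' argmin (sub-nm grid after local parabolic refinement). Pairs whose
#' argmin sits on the boundary of the valid range are flagged invalid.
#'
#' @param wx,wy measured Gaussian sigma widths in µm (vectors).
#' @param calib an [build_z_calibration()] object.
#' @return A list with `z` (µm) and `valid` (logical).
#' @export
z_from_widths <- function(wx, wy, calib) {
  if (!inherits(calib, "spt_zcal")) stop("calibration missing or invalid")
  stopifnot(all(wx > 0), all(wy > 0), length(wx) == length(wy))
  zr <- calib$valid_range
  grid <- seq(zr[1], zr[2], by = 0.001)
  cx <- sqrt(calib$wx_fun(grid))
  cy <- sqrt(calib$wy_fun(grid))
  n <- length(wx)
  z <- numeric(n)
  valid <- logical(n)
  sx <- sqrt(wx); sy <- sqrt(wy)
  for (i in seq_len(n)) {
    d2 <- (cx - sx[i])^2 + (cy - sy[i])^2
    k <- which.min(d2)
    if (k == 1 || k == length(grid)) {
      z[i] <- grid[k]
      valid[i] <- FALSE
    } else {
      # parabolic refinement through the three grid points around the min
      num <- d2[k - 1] - d2[k + 1]
      den <- d2[k - 1] - 2 * d2[k] + d2[k + 1]
      off <- if (den > 0) 0.5 * num / den else 0
      z[i] <- grid[k] + off * 0.001
      valid[i] <- TRUE
    }
  }
  list(z = z, valid = valid)
}
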