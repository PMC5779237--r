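# Astigmatic PSF model and frame renderer. A cylindrical lens in the
# detection path makes the spot width along x and y depend on defocus with
# opposite sign, so the width asymmetry encodes z.

#' Astigmatic Gaussian PSF model
#'
#' Defocus curves of the form
#' `w(z) = w0 * sqrt(1 + ((z -/+ gamma) / depth)^2)` for the x and y widths
#' (Gaussian sigma, µm). The two curves cross at z = 0 and are monotone on
#' opposite sides of the crossing inside the valid range.
#'
#' @param w0 in-focus Gaussian sigma in µm.
#' @param gamma astigmatic focal offset in µm (the x and y focal planes sit
#'   at +gamma and -gamma).
#' @param depth defocus depth scale in µm.
#' @param pixel_size camera pixel size in µm.
#' @param z_range valid z range in µm (length-2).
#' @return An object of class `spt_psf` with functions `wx(z)` and `wy(z)`.
#' @examples
#' psf <- psf_model()
#' psf$wx(0) == psf$wy(0)
#' @export
psf_model <- function(w0 = 0.13, gamma = 0.25, depth = 0.4,
                      pixel_size = 0.1, z_range = c(-0.4, 0.4)) {
  stopifnot(w0 > 0, depth > 0, pixel_size > 0)
  force(w0); force(gamma); force(depth)
  structure(
    list(
      w0 = w0, gamma = gamma, depth = depth, pixel_size = pixel_size,
      z_range = z_range,
      wx = function(z) w0 * sqrt(1 + ((z - gamma) / depth)^2),
      wy = function(z) w0 * sqrt(1 + ((z + gamma) / depth)^2)
    ),
    class = "spt_psf"
  )
}

# expected photon count per pixel for one emitter, by exact integration of
# the elliptical Gaussian over pixel areas (so the image sums to n_photons
# up to boundary truncation)
render_emitter <- function(img, x0, y0, wx, wy, photons, pixel_size) {
  nr <- nrow(img); nc <- ncol(img)
  xe <- (0:nc) * pixel_size
  ye <- (0:nr) * pixel_size
  px <- diff(stats::pnorm(xe, mean = x0, sd = wx))
  py <- diff(stats::pnorm(ye, mean = y0, sd = wy))
  img + photons * outer(py, px)
}

#' Render image frames from emitter positions
#'
#' Each emitter is rendered as an elliptical 2D Gaussian with widths
#' `wx(z)`, `wy(z)` from the astigmatic PSF model, integrated over pixels.
#' Poisson shot noise is applied to signal plus background, then Gaussian
#' read noise is added.
#'
#' @param emitters `data.frame` with `frame`, `x`, `y`, `z` (µm) and
#'   optionally `photons`.
#' @param psf a [psf_model()].
#' @param img_size integer 2-vector: image size in pixels (rows, cols).
#' @param photons photon count per emitter used when `emitters` has no
#'   `photons` column (> 0).
#' @param background background level in photons/pixel.
#' @param read_noise Gaussian read noise sd in photons.
#' @param noiseless if `TRUE`, return expected counts without noise.
#' @param seed integer seed.
#' @return A 3D array `[row, col, frame]` of counts. Pixel (r, c) is
#'   centered at `x = (c - 0.5) * pixel_size`, `y = (r - 0.5) * pixel_size`.
#' @export
render_frames <- function(emitters, psf = psf_model(),
                          img_size = c(32, 32), photons = 3000,
                          background = 5, read_noise = 1,
                          noiseless = FALSE, seed = 1) {
  stopifnot(is.data.frame(emitters),
            all(c("frame", "x", "y", "z") %in% names(emitters)),
            photons > 0, background >= 0, read_noise >= 0)
  px <- psf$pixel_size
  fx <- img_size[2] * px
  fy <- img_size[1] * px
  if (nrow(emitters) > 0 &&
      (any(emitters$x < 0 | emitters$x > fx) ||
       any(emitters$y < 0 | emitters$y > fy))) {
    stop("emitter outside field (", fx, " x ", fy, " um)")
  }
  if (!"photons" %in% names(emitters)) emitters$photons <- photons
  frames <- sort(unique(emitters$frame))
  n_frames <- if (length(frames)) max(frames) else 1L
  out <- array(background, c(img_size[1], img_size[2], n_frames))
  for (f in frames) {
    sub <- emitters[emitters$frame == f, , drop = FALSE]
    img <- out[, , f]
    for (i in seq_len(nrow(sub))) {
      img <- render_emitter(img, sub$x[i], sub$y[i],
                            psf$wx(sub$z[i]), psf$wy(sub$z[i]),
                            sub$photons[i], px)
    }
    out[, , f] <- img
  }
  if (!noiseless) {
    with_seed(derive_seed(seed, "render"), {
      n <- length(out)
      out[] <- rpois(n, out) + rnorm(n, sd = read_noise)
    })
  }
  out
}
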