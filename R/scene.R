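#' Generate a synthetic dendritic scene
#'
#' Places post-synaptic density (PSD) centers in the imaging field with a
#' minimum pairwise spacing, and attaches one (occasionally more) nanodomain
#' to each PSD. Nanodomain centers sit a short distance from their PSD
#' center (|offset| drawn around 150 nm, capped at 250 nm), reflecting the
#' sub-synaptic position of receptor confinement zones. A dendrite axis is
#' included for orientation; extrasynaptic tracks are placed relative to
#' PSDs, not the axis.
#'
#' @param n_psd number of PSDs to place.
#' @param field_size field extent per axis in µm (length-3); PSDs are placed
#'   in x/y with z drawn in a thin slab.
#' @param min_spacing minimum pairwise PSD distance in µm (default 2).
#' @param nanodomain_offset_mean,nanodomain_offset_sd mean and sd (µm) of
#'   the nanodomain offset magnitude from the PSD center.
#' @param p_extra_nanodomain probability that a PSD carries a second
#'   nanodomain.
#' @param seed integer seed; the scene is deterministic given the seed.
#' @return An object of class `spt_scene`: list with `psd_centers` (n x 3
#'   matrix, µm), `nanodomains` (data.frame with `psd`, `x`, `y`, `z`),
#'   `dendrite_axis` (2 x 3 matrix), `field_size`, `seed`.
#' @examples
#' sc <- make_scene(n_psd = 3, field_size = c(10, 10, 1), seed = 1)
#' nrow(sc$psd_centers)
#' @export
make_scene <- function(n_psd,
                       field_size = c(20, 20, 1),
                       min_spacing = 2.0,
                       nanodomain_offset_mean = 0.15,
                       nanodomain_offset_sd = 0.042,
                       p_extra_nanodomain = 0.15,
                       seed = 1) {
  stopifnot(n_psd >= 1, length(field_size) == 3, all(field_size > 0),
            min_spacing >= 0)
  # pigeonhole feasibility: at most one PSD per min_spacing cell
  n_cells <- prod(floor(field_size[1:2] / max(min_spacing, 1e-6)) + 1)
  if (n_psd > n_cells) {
    stop("infeasible packing: ", n_psd, " PSDs cannot fit in a ",
         field_size[1], " x ", field_size[2], " um field with ",
         min_spacing, " um spacing")
  }
  with_seed(derive_seed(seed, "scene"), {
    centers <- matrix(NA_real_, 0, 3)
    tries <- 0
    max_tries <- 2000 * n_psd
    while (nrow(centers) < n_psd) {
      tries <- tries + 1
      if (tries > max_tries) {
        stop("infeasible packing: could not place ", n_psd,
             " PSDs with ", min_spacing, " um spacing after ",
             max_tries, " attempts")
      }
      cand <- c(runif(1, 0, field_size[1]),
                runif(1, 0, field_size[2]),
                runif(1, 0.35 * field_size[3], 0.65 * field_size[3]))
      ok <- nrow(centers) == 0 ||
        all(sqrt(colSums((t(centers[, 1:2, drop = FALSE]) - cand[1:2])^2)) >=
              min_spacing)
      if (ok) centers <- rbind(centers, cand)
    }
    rownames(centers) <- NULL
    colnames(centers) <- c("x", "y", "z")

    nd <- do.call(rbind, lapply(seq_len(n_psd), function(i) {
      k <- 1 + rbinom(1, 1, p_extra_nanodomain)
      off <- sapply(seq_len(k), function(j) {
        r <- min(abs(rnorm(1, nanodomain_offset_mean, nanodomain_offset_sd)),
                 0.25)
        u <- rnorm(3)
        u[3] <- u[3] * 0.3  # nanodomains lie close to the PSD plane
        u <- u / sqrt(sum(u^2))
        centers[i, ] + r * u
      })
      data.frame(psd = i, x = off[1, ], y = off[2, ], z = off[3, ])
    }))
    rownames(nd) <- NULL

    axis_y <- runif(1, 0.3, 0.7) * field_size[2]
    dendrite_axis <- rbind(c(0, axis_y, field_size[3] / 2),
                           c(field_size[1], axis_y, field_size[3] / 2))

    structure(
      list(psd_centers = centers, nanodomains = nd,
           dendrite_axis = dendrite_axis, field_size = field_size,
           seed = seed),
      class = "spt_scene"
    )
  })
}

#' @export
print.spt_scene <- function(x, ...) {
  cat("Synthetic scene:", nrow(x$psd_centers), "PSDs,",
      nrow(x$nanodomains), "nanodomains in a",
      paste(x$field_size, collapse = " x "), "um field (seed",
      paste0(x$seed, ")\n"))
  invisible(x)
}
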