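# Stage-drift estimation from fiducial-pattern traces and inter-channel
# chromatic registration from nanohole grids.

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  half <- floor(window / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Estimate stage drift from fiducial traces
#'
#' Each fiducial's per-frame displacement from its own time-mean estimates
#' the common stage drift; the per-frame robust average (median across
#' fiducials) is smoothed with a centered moving average and zeroed at the
#' reference frame. Because the fiducial pattern itself is stationary, the
#' residual error scales as noise / sqrt(n_fiducials).
#'
#' @param fiducial_table `data.frame` with `frame`, `fiducial`, `x`, `y`,
#'   `z` (µm), or an `spt_fiducials` object.
#' @param smoothing_window moving-average window in frames (default 10).
#' @param reference_frame frame at which the drift is defined to be zero.
#' @return An object of class `spt_drift`: `data.frame` with `frame`, `dx`,
#'   `dy`, `dz` (µm).
#' @export
estimate_drift <- function(fiducial_table, smoothing_window = 10,
                           reference_frame = NULL) {
  if (inherits(fiducial_table, "spt_fiducials")) {
    fiducial_table <- fiducial_table$table
  }
  stopifnot(all(c("frame", "fiducial", "x", "y", "z") %in%
                  names(fiducial_table)))
  frames <- sort(unique(fiducial_table$frame))
  per_fid <- split(fiducial_table, fiducial_table$fiducial)
  full <- vapply(per_fid, function(d) length(unique(d$frame)) == length(frames),
                 logical(1))
  if (!any(full)) stop("no fiducial visible in every frame")
  per_fid <- per_fid[full]
  disp <- lapply(per_fid, function(d) {
    d <- d[order(d$frame), ]
    cbind(d$x - mean(d$x), d$y - mean(d$y), d$z - mean(d$z))
  })
  n_frames <- length(frames)
  med <- sapply(1:3, function(ax) {
    m <- vapply(disp, function(m) m[, ax], numeric(n_frames))
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    apply(m, 1, stats::median)
  })
  sm <- apply(med, 2, moving_average, window = smoothing_window)
  if (is.null(reference_frame)) reference_frame <- frames[1]
  ref_idx <- match(reference_frame, frames)
  if (is.na(ref_idx)) stop("reference frame not present")
  sm <- sweep(sm, 2, sm[ref_idx, ])
  out <- data.frame(frame = frames, dx = sm[, 1], dy = sm[, 2], dz = sm[, 3])
  class(out) <- c("spt_drift", "data.frame")
  out
}

#' Apply a drift correction to a localization table
#'
#' Corrected position = raw position - drift(frame). Record count is
#' preserved. Note the operation is not idempotent: applying the same trace
#' twice shifts positions by -drift again.
#'
#' @param localizations `data.frame` with `frame`, `x`, `y` and optionally
#'   `z`.
#' @param drift an [estimate_drift()] result (or any data.frame with
#'   `frame`, `dx`, `dy`, `dz`).
#' @return The corrected localization table.
#' @export
apply_drift_correction <- function(localizations, drift) {
  stopifnot(all(c("frame", "x", "y") %in% names(localizations)))
  idx <- match(localizations$frame, drift$frame)
  if (anyNA(idx)) stop("localization frames outside the drift trace domain")
  localizations$x <- localizations$x - drift$dx[idx]
  localizations$y <- localizations$y - drift$dy[idx]
  if ("z" %in% names(localizations)) {
    localizations$z <- localizations$z - drift$dz[idx]
  }
  localizations
}

poly2d_basis <- function(x, y, degree) {
  cols <- list()
  for (i in 0:degree) {
    for (j in 0:(degree - i)) {
      cols[[length(cols) + 1]] <- x^i * y^j
    }
  }
  do.call(cbind, cols)
}

#' Fit a chromatic mapping function from matched channel pairs
#'
#' Least-squares 2D polynomial per axis mapping source-channel positions to
#' the target channel. The residual is always evaluated on a held-out split
#' (default 20% of pairs), since training residuals understate the mapping
#' error. The map is fitted at focus; its validity in z is bounded
#' (default ±400 nm) and out-of-range points are flagged, not dropped, by
#' [apply_map()].
#'
#' @param pairs matched positions: a `spt_nanoholes` object or a
#'   `data.frame` with `x1`, `y1` (source) and `x2`, `y2` (target), µm.
#' @param degree polynomial degree (>= 1, default 2).
#' @param holdout_fraction fraction of pairs held out for validation.
#' @param z_valid validity range in z (µm).
#' @param seed seed for the held-out split.
#' @return An object of class `spt_chromatic_map`: coefficient matrix,
#'   `degree`, `residual_rms` (µm, held-out RMS pair distance), `z_valid`.
#' @export
fit_chromatic_map <- function(pairs, degree = 2, holdout_fraction = 0.2,
                              z_valid = c(-0.4, 0.4), seed = 1) {
  if (inherits(pairs, "spt_nanoholes")) {
    pairs <- data.frame(x1 = pairs$ch1$x, y1 = pairs$ch1$y,
                        x2 = pairs$ch2$x, y2 = pairs$ch2$y)
  }
  stopifnot(all(c("x1", "y1", "x2", "y2") %in% names(pairs)), degree >= 1)
  n <- nrow(pairs)
  n_coef <- (degree + 1) * (degree + 2) / 2
  if (n * (1 - holdout_fraction) < n_coef) {
    stop("need at least ", ceiling(n_coef / (1 - holdout_fraction)),
         " matched pairs for degree ", degree)
  }
  test_idx <- if (holdout_fraction > 0) {
    with_seed(derive_seed(seed, "chromatic-holdout"),
              sample.int(n, max(1, round(holdout_fraction * n))))
  } else integer()
  train_idx <- setdiff(seq_len(n), test_idx)
  B <- poly2d_basis(pairs$x1, pairs$y1, degree)
  if (qr(B[train_idx, , drop = FALSE])$rank < n_coef) {
    stop("degenerate pair geometry: polynomial basis is rank-deficient")
  }
  fit_x <- stats::lm.fit(B[train_idx, , drop = FALSE], pairs$x2[train_idx])
  fit_y <- stats::lm.fit(B[train_idx, , drop = FALSE], pairs$y2[train_idx])
  coefs <- cbind(x = fit_x$coefficients, y = fit_y$coefficients)
  residual_rms <- if (length(test_idx)) {
    pred <- B[test_idx, , drop = FALSE] %*% coefs
    sqrt(mean((pred[, 1] - pairs$x2[test_idx])^2 +
                (pred[, 2] - pairs$y2[test_idx])^2))
  } else NA_real_
  structure(
    list(coefficients = coefs, degree = degree,
         residual_rms = residual_rms, z_valid = z_valid,
         n_train = length(train_idx), n_test = length(test_idx)),
    class = "spt_chromatic_map"
  )
}

#' @export
print.spt_chromatic_map <- function(x, ...) {
  cat(sprintf(
    "Chromatic map: degree %d, held-out RMS residual %.2f nm (%d train / %d test pairs), valid z %.0f..%.0f nm\n",
    x$degree, 1000 * x$residual_rms, x$n_train, x$n_test,
    1000 * x$z_valid[1], 1000 * x$z_valid[2]))
  invisible(x)
}

#' Apply a chromatic mapping function to localizations
#'
#' Transforms source-channel x/y positions into the target channel frame.
#' Points whose z lies outside the map's validity range are flagged in a
#' `map_valid` column, never dropped.
#'
#' @param localizations `data.frame` with `x`, `y` and optionally `z`,
#'   `channel`.
#' @param map an [fit_chromatic_map()] object.
#' @param channel if `localizations` has a `channel` column, the source
#'   channel the map expects (error on mismatch).
#' @return The transformed table with a `map_valid` logical column.
#' @export
apply_map <- function(localizations, map, channel = NULL) {
  stopifnot(inherits(map, "spt_chromatic_map"),
            all(c("x", "y") %in% names(localizations)))
  if (!is.null(channel) && "channel" %in% names(localizations) &&
      !all(localizations$channel == channel)) {
    stop("channel mismatch: map expects source channel ", channel)
  }
  B <- poly2d_basis(localizations$x, localizations$y, map$degree)
  pred <- B %*% map$coefficients
  localizations$x <- pred[, 1]
  localizations$y <- pred[, 2]
  localizations$map_valid <- if ("z" %in% names(localizations)) {
    localizations$z >= map$z_valid[1] & localizations$z <= map$z_valid[2]
  } else TRUE
  localizations
}
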