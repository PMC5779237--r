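# Per-trajectory mobility statistics: time-averaged MSD, the diffusion
# coefficient from a line through the first MSD points, and the trajectory
# range (maximum per-axis coordinate span).

#' Time-averaged mean squared displacement of one trajectory
#'
#' `msd(k dt) = mean over i of |r(i+k) - r(i)|^2` using every pair of
#' points k frames apart. Lags are in frame units, so tracks with gaps
#' contribute only the pairs they actually have.
#'
#' @param trajectory `data.frame` with `frame`, `x`, `y` and optionally
#'   `z`.
#' @param max_lag largest lag (frames) to evaluate; default
#'   `n_frames - 1`.
#' @param frame_interval frame interval in s; taken from the trajectory's
#'   attribute when present.
#' @return An object of class `spt_msd`: `data.frame` with `lag` (frames),
#'   `tau` (s), `msd` (µm²), `count` (pairs per lag), including the lag-0
#'   row.
#' @export
msd <- function(trajectory, max_lag = NULL, frame_interval = NULL) {
  stopifnot(all(c("frame", "x", "y") %in% names(trajectory)))
  if (nrow(trajectory) < 5) stop("too-short track: need >= 5 points")
  if (is.null(frame_interval)) {
    frame_interval <- attr(trajectory, "frame_interval")
    if (is.null(frame_interval)) frame_interval <- 1
  }
  tr <- trajectory[order(trajectory$frame), ]
  pos <- cbind(tr$x, tr$y, if ("z" %in% names(tr)) tr$z else 0)
  fr <- tr$frame
  if (is.null(max_lag)) max_lag <- max(fr) - min(fr)
  lags <- 0:max_lag
  out <- data.frame(lag = lags, tau = lags * frame_interval,
                    msd = NA_real_, count = 0L)
  out$msd[1] <- 0
  out$count[1] <- nrow(tr)
  n <- nrow(tr)
  for (k in seq_len(max_lag)) {
    # pairs exactly k frames apart
    ii <- seq_len(n)
    jj <- match(fr + k, fr)
    ok <- !is.na(jj)
    if (!any(ok)) next
    d2 <- rowSums((pos[jj[ok], , drop = FALSE] - pos[ii[ok], , drop = FALSE])^2)
    out$msd[k + 1] <- mean(d2)
    out$count[k + 1] <- sum(ok)
  }
  class(out) <- c("spt_msd", "data.frame")
  out
}

#' Diffusion coefficient from the first points of an MSD curve
#'
#' Weighted least-squares line (weights = pair counts, an inverse-variance
#' proxy) through the first `n_points` nonzero lags, with a free intercept
#' that absorbs the localization-noise offset. For 3D data the slope equals
#' `6 D`; for 2D, `4 D`. A negative slope is floored to zero and flagged.
#'
#' @param msd_curve an [msd()] result (or `data.frame` with `tau`, `msd`,
#'   `count`).
#' @param n_points number of lags fitted (default 4).
#' @param dims 2 or 3 (default 3).
#' @return A list of class `spt_dfit`: `d_coeff` (µm²/s), `slope`,
#'   `intercept`, `flagged` (TRUE when the slope was negative).
#' @export
fit_diffusion <- function(msd_curve, n_points = 4, dims = 3) {
  stopifnot(dims %in% c(2, 3))
  pts <- msd_curve[msd_curve$lag > 0 & !is.na(msd_curve$msd), , drop = FALSE]
  if (nrow(pts) < n_points) {
    stop("MSD curve has fewer than ", n_points, " usable lags")
  }
  pts <- pts[seq_len(n_points), ]
  w <- pts$count
  fit <- stats::lm.wfit(cbind(1, pts$tau), pts$msd, w)
  slope <- fit$coefficients[2]
  flagged <- slope < 0
  d <- max(slope, 0) / (2 * dims)
  structure(
    list(d_coeff = unname(d), slope = unname(slope),
         intercept = unname(fit$coefficients[1]), flagged = flagged,
         n_points = n_points, dims = dims),
    class = "spt_dfit"
  )
}

#' Trajectory range
#'
#' The coordinate span (max - min) is computed along each axis and the
#' maximum of the per-axis spans is returned.
#'
#' @param trajectory `data.frame` with `x`, `y` and optionally `z`, or an
#'   n x d position matrix.
#' @return Range in µm (0 for a single point).
#' @export
trajectory_range <- function(trajectory) {
  pos <- if (is.matrix(trajectory)) trajectory else
    cbind(trajectory$x, trajectory$y,
          if ("z" %in% names(trajectory)) trajectory$z)
  if (nrow(pos) == 0) stop("empty trajectory")
  max(apply(pos, 2, function(v) diff(range(v))))
}

#' Per-trajectory mobility metrics for a set of tracks
#'
#' Computes, for every track: the diffusion coefficient from the
#' first-`n_points` MSD fit, its log10, the trajectory range, the mean
#' position and the number of points. Tracks shorter than `min_length`
#' frames are skipped and counted. Uses a vectorized path when all tracks
#' share the same consecutive frame grid (the simulator output), and the
#' generic per-track path otherwise.
#'
#' @param tracks long `data.frame` (`track`, `frame`, `x`, `y`, `z`), an
#'   `spt_tracks` or `spt_population` object.
#' @param frame_interval frame interval in s.
#' @param n_points MSD lags fitted (default 4).
#' @param dims 2 or 3.
#' @param min_length minimum track length in points (default 10).
#' @return A `data.frame` of class `spt_metrics` with `track`, `d_coeff`,
#'   `log10_d`, `trajectory_range`, `mean_x`, `mean_y`, `mean_z`,
#'   `n_frames`, `d_flagged`; attribute `n_skipped`.
#' @export
compute_metrics <- function(tracks, frame_interval = NULL, n_points = 4,
                            dims = 3, min_length = 10) {
  if (inherits(tracks, "spt_population")) {
    if (is.null(frame_interval)) frame_interval <- tracks$frame_interval
    tracks <- tracks$tracks
  }
  if (inherits(tracks, "spt_tracks")) tracks <- tracks$tracks
  if (is.null(frame_interval)) frame_interval <- 1
  stopifnot(all(c("track", "frame", "x", "y") %in% names(tracks)))
  if (!"z" %in% names(tracks)) tracks$z <- 0
  tracks <- tracks[order(tracks$track, tracks$frame), ]
  runs <- rle(tracks$track)
  lens <- runs$lengths
  ids <- runs$values
  regular <- length(unique(lens)) == 1 &&
    all(tracks$frame == rep(seq_len(lens[1]), length(lens)))
  n_skipped <- 0L
  if (regular && lens[1] >= max(min_length, n_points + 1)) {
    nf <- as.integer(lens[1])
    nt <- length(lens)
    X <- matrix(tracks$x, nf, nt)
    Y <- matrix(tracks$y, nf, nt)
    Z <- matrix(tracks$z, nf, nt)
    M <- matrix(NA_real_, n_points, nt)
    for (k in seq_len(n_points)) {
      i1 <- seq_len(nf - k)
      i2 <- i1 + k
      M[k, ] <- colMeans((X[i2, , drop = FALSE] - X[i1, , drop = FALSE])^2 +
                         (Y[i2, , drop = FALSE] - Y[i1, , drop = FALSE])^2 +
                         (Z[i2, , drop = FALSE] - Z[i1, , drop = FALSE])^2)
    }
    tau <- seq_len(n_points) * frame_interval
    w <- nf - seq_len(n_points)
    sw <- sum(w)
    tw <- sum(w * tau) / sw
    denom <- sum(w * (tau - tw)^2)
    slope <- as.vector(crossprod(w * (tau - tw), M)) / denom
    d <- pmax(slope, 0) / (2 * dims)
    rng <- pmax(apply(X, 2, function(v) diff(range(v))),
                apply(Y, 2, function(v) diff(range(v))),
                apply(Z, 2, function(v) diff(range(v))))
    out <- data.frame(
      track = ids,
      d_coeff = d,
      log10_d = ifelse(d > 0, log10(d), NA_real_),
      trajectory_range = rng,
      mean_x = colMeans(X), mean_y = colMeans(Y), mean_z = colMeans(Z),
      n_frames = nf,
      d_flagged = slope < 0
    )
  } else {
    per <- split(tracks, tracks$track)
    rows <- lapply(per, function(tr) {
      if (nrow(tr) < max(min_length, n_points + 1)) return(NULL)
      mc <- msd(tr, max_lag = n_points, frame_interval = frame_interval)
      if (sum(mc$lag > 0 & !is.na(mc$msd)) < n_points) return(NULL)
      ft <- fit_diffusion(mc, n_points, dims)
      data.frame(
        track = tr$track[1],
        d_coeff = ft$d_coeff,
        log10_d = if (ft$d_coeff > 0) log10(ft$d_coeff) else NA_real_,
        trajectory_range = trajectory_range(tr),
        mean_x = mean(tr$x), mean_y = mean(tr$y), mean_z = mean(tr$z),
        n_frames = nrow(tr),
        d_flagged = ft$flagged
      )
    })
    n_skipped <- sum(vapply(rows, is.null, logical(1)))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(track = integer(), d_coeff = numeric(),
                 log10_d = numeric(), trajectory_range = numeric(),
                 mean_x = numeric(), mean_y = numeric(), mean_z = numeric(),
                 n_frames = integer(), d_flagged = logical())
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("spt_metrics", "data.frame")
  out
}
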