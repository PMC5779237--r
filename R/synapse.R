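# PSD identification from PALM tables, distance-based synaptic
# classification of trajectories, distance histograms, and rigid alignment
# of timed epochs.

# cell-list neighbor search: indices of points within eps of each query
build_cells <- function(pos, eps) {
  cells <- floor(sweep(pos, 2, apply(pos, 2, min)) / eps)
  key <- paste(cells[, 1], cells[, 2], cells[, 3])
  list(index = split(seq_len(nrow(pos)), key), cells = cells)
}

neighbors_of <- function(i, pos, cl, eps) {
  ci <- cl$cells[i, ]
  cand <- integer()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    k <- paste(ci[1] + dx, ci[2] + dy, ci[3] + dz)
    hit <- cl$index[[k]]
    if (!is.null(hit)) cand <- c(cand, hit)
  }
  d2 <- (pos[cand, 1] - pos[i, 1])^2 + (pos[cand, 2] - pos[i, 2])^2 +
    (pos[cand, 3] - pos[i, 3])^2
  cand[d2 <= eps^2]
}

#' Identify PSD clusters in a PALM localization table
#'
#' Density-based clustering (radius / minimum-neighbor rule): points with
#' at least `min_points` neighbors within `neighborhood_radius` are core
#' points; density-connected core points form clusters, border points join
#' the cluster of a neighboring core, and everything else is background.
#' Cluster centers are member centroids.
#'
#' @param localizations `data.frame` with `x`, `y` and optionally `z` (µm).
#' @param neighborhood_radius neighbor radius in µm (default 0.1).
#' @param min_points minimum neighbors (self included) for a core point
#'   (default 20).
#' @return A list of class `spt_clusters`: `clusters` (`data.frame` with
#'   `cluster`, `x`, `y`, `z`, `n`, `sd_x`, `sd_y`, `sd_z`), `assignment`
#'   (per-localization cluster index, 0 = background).
#' @export
cluster_palm <- function(localizations, neighborhood_radius = 0.1,
                         min_points = 20) {
  stopifnot(nrow(localizations) > 0,
            all(c("x", "y") %in% names(localizations)))
  pos <- cbind(localizations$x, localizations$y,
               if ("z" %in% names(localizations)) localizations$z else 0)
  n <- nrow(pos)
  eps <- neighborhood_radius
  cl <- build_cells(pos, eps)
  nb <- vector("list", n)
  is_core <- logical(n)
  for (i in seq_len(n)) {
    nb[[i]] <- neighbors_of(i, pos, cl, eps)
    is_core[i] <- length(nb[[i]]) >= min_points
  }
  assignment <- integer(n)
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || assignment[i] != 0L) next
    cluster_id <- cluster_id + 1L
    queue <- i
    assignment[i] <- cluster_id
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      for (q in nb[[j]]) {
        if (assignment[q] == 0L) {
          assignment[q] <- cluster_id
          if (is_core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  clusters <- if (cluster_id > 0) {
    do.call(rbind, lapply(seq_len(cluster_id), function(cid) {
      m <- pos[assignment == cid, , drop = FALSE]
      data.frame(cluster = cid, x = mean(m[, 1]), y = mean(m[, 2]),
                 z = mean(m[, 3]), n = nrow(m),
                 sd_x = stats::sd(m[, 1]), sd_y = stats::sd(m[, 2]),
                 sd_z = stats::sd(m[, 3]))
    }))
  } else {
    data.frame(cluster = integer(), x = numeric(), y = numeric(),
               z = numeric(), n = integer(), sd_x = numeric(),
               sd_y = numeric(), sd_z = numeric())
  }
  structure(list(clusters = clusters, assignment = assignment,
                 neighborhood_radius = neighborhood_radius,
                 min_points = min_points),
            class = "spt_clusters")
}

#' @export
print.spt_clusters <- function(x, ...) {
  cat("Density clustering:", nrow(x$clusters), "clusters,",
      sum(x$assignment == 0), "background points\n")
  invisible(x)
}

# per-track mean and min distances to every cluster center; returns a list
# of two n_tracks x n_clusters matrices
track_cluster_distances <- function(tracks, centers) {
  runs <- rle(tracks$track)
  nt <- length(runs$values)
  pos <- cbind(tracks$x, tracks$y,
               if ("z" %in% names(tracks)) tracks$z else 0)
  grp <- rep(seq_len(nt), runs$lengths)
  len <- runs$lengths
  idx <- split(seq_len(nrow(pos)), grp)
  mean_d <- matrix(NA_real_, nt, nrow(centers))
  min_d <- matrix(NA_real_, nt, nrow(centers))
  for (c in seq_len(nrow(centers))) {
    d <- sqrt((pos[, 1] - centers[c, 1])^2 +
              (pos[, 2] - centers[c, 2])^2 +
              (pos[, 3] - centers[c, 3])^2)
    mean_d[, c] <- rowsum(d, grp, reorder = FALSE)[, 1] / len
    min_d[, c] <- vapply(idx, function(ii) min(d[ii]), numeric(1))
  }
  list(mean = mean_d, min = min_d, track_ids = runs$values)
}

#' Classify trajectories as synaptic
#'
#' A synapse is a candidate for a trajectory when the trajectory passes
#' within `candidate_radius` of its center. Among candidates, the nearest
#' center is the one minimizing the trajectory-mean distance (fixed per
#' trajectory), and the trajectory is synaptic when that mean distance is
#' below the rule threshold. With no candidate (or no clusters at all) the
#' trajectory is non-synaptic.
#'
#' @param tracks long `data.frame` (`track`, `frame`, `x`, `y`, `z`), an
#'   `spt_tracks`/`spt_population` object, or a single trajectory without a
#'   `track` column.
#' @param clusters an [cluster_palm()] result or a `data.frame` of centers
#'   (`x`, `y`, `z`).
#' @param rule an [synaptic_rule()] object.
#' @return `data.frame` with `track`, `synaptic`, `nearest_cluster`
#'   (index or `NA`), `mean_distance` (µm, to the nearest candidate center,
#'   or nearest center overall when no candidate).
#' @export
classify_synaptic <- function(tracks, clusters, rule = synaptic_rule()) {
  if (inherits(tracks, "spt_population")) tracks <- tracks$tracks
  if (inherits(tracks, "spt_tracks")) tracks <- tracks$tracks
  if (!"track" %in% names(tracks)) tracks$track <- 1L
  centers <- cluster_centers(clusters)
  tracks <- tracks[order(tracks$track, tracks$frame), ]
  ids <- rle(tracks$track)$values
  if (nrow(centers) == 0) {
    return(data.frame(track = ids, synaptic = FALSE,
                      nearest_cluster = NA_integer_,
                      mean_distance = NA_real_))
  }
  dd <- track_cluster_distances(tracks, as.matrix(centers))
  cand <- dd$min <= rule$candidate_radius
  mean_gated <- dd$mean
  mean_gated[!cand] <- Inf
  nearest <- apply(mean_gated, 1, which.min)
  best <- mean_gated[cbind(seq_along(nearest), nearest)]
  has_cand <- is.finite(best)
  # fall back to the globally nearest center for reporting
  fallback <- apply(dd$mean, 1, which.min)
  nearest[!has_cand] <- fallback[!has_cand]
  best[!has_cand] <- dd$mean[cbind(which(!has_cand), fallback[!has_cand])]
  data.frame(
    track = dd$track_ids,
    synaptic = has_cand & best < rule$mean_distance_threshold,
    nearest_cluster = as.integer(nearest),
    mean_distance = best
  )
}

cluster_centers <- function(clusters) {
  if (inherits(clusters, "spt_clusters")) clusters <- clusters$clusters
  if (is.matrix(clusters)) {
    clusters <- as.data.frame(clusters)
    names(clusters)[1:ncol(clusters)] <- c("x", "y", "z")[1:ncol(clusters)]
  }
  if (nrow(clusters) == 0) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric()))
  }
  if (!"z" %in% names(clusters)) clusters$z <- 0
  clusters[, c("x", "y", "z")]
}

#' Distance-to-PSD fractions and histogram
#'
#' Each trajectory's representative distance is the mean distance of its
#' points to the nearest cluster center (the center minimizing that mean).
#' Reports the share of trajectories within each radius — monotone
#' non-decreasing in the radius — and a distance histogram.
#'
#' @param tracks as in [classify_synaptic()].
#' @param clusters an [cluster_palm()] result or center table.
#' @param radii radii in µm (default 0.5 and 1.0).
#' @param bin_width histogram bin width in µm.
#' @return A list of class `spt_distances`: `fractions` (named by radius),
#'   `distances` (per track), `histogram` (`data.frame` with `mid`,
#'   `count`).
#' @export
distance_fractions <- function(tracks, clusters, radii = c(0.5, 1.0),
                               bin_width = 0.1) {
  if (inherits(tracks, "spt_population")) tracks <- tracks$tracks
  if (inherits(tracks, "spt_tracks")) tracks <- tracks$tracks
  if (!"track" %in% names(tracks)) tracks$track <- 1L
  stopifnot(nrow(tracks) > 0)
  centers <- cluster_centers(clusters)
  if (nrow(centers) == 0) stop("empty cluster list")
  tracks <- tracks[order(tracks$track, tracks$frame), ]
  dd <- track_cluster_distances(tracks, as.matrix(centers))
  dist <- apply(dd$mean, 1, min)
  fr <- vapply(radii, function(r) mean(dist <= r), numeric(1))
  breaks <- seq(0, max(dist) + bin_width, by = bin_width)
  h <- hist(dist, breaks = breaks, plot = FALSE)
  structure(
    list(fractions = stats::setNames(fr, paste0("within_", radii, "um")),
         distances = stats::setNames(dist, dd$track_ids),
         histogram = data.frame(mid = h$mids, count = h$counts)),
    class = "spt_distances"
  )
}

#' @export
print.spt_distances <- function(x, ...) {
  cat("Distance to nearest PSD center over", length(x$distances),
      "trajectories:\n")
  for (nm in names(x$fractions)) {
    cat(sprintf("  %s: %.1f%%\n", nm, 100 * x$fractions[[nm]]))
  }
  invisible(x)
}

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}
rot_x <- function(phi) {
  c <- cos(phi); s <- sin(phi)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

kabsch <- function(a, b) {
  # least-squares rotation R and translation t with b ~ a %*% t(R) + t
  ca <- colMeans(a); cb <- colMeans(b)
  H <- crossprod(sweep(a, 2, ca), sweep(b, 2, cb))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - as.vector(R %*% ca)
  list(R = R, t = t)
}

#' Rigid alignment of two epoch point clouds
#'
#' Least-squares rigid transform (rotation + translation, no scaling)
#' mapping epoch A onto epoch B. With equal-sized inputs the points are
#' taken as corresponding; otherwise correspondence is established by
#' iterated nearest-neighbor matching after centroid alignment. The
#' rotation is reported as two angles about the viewing axes: in-plane
#' (about z) and out-of-plane (about x), from the decomposition
#' `R = Rx(phi) %*% Rz(theta)`.
#'
#' @param epoch_a,epoch_b n x 3 matrices or `data.frame`s with `x`, `y`,
#'   `z` (µm); each needs >= 3 non-collinear points.
#' @param overlap_tol distance tolerance in µm for the overlap score
#'   (default 0.05).
#' @param max_icp_iter nearest-neighbor matching iterations for unpaired
#'   inputs.
#' @return An object of class `spt_alignment`: `translation` (µm, 3-vector
#'   applied after rotation about the epoch-A centroid), `rotation_deg`
#'   (`theta_z`, `phi_x`), `rms` (µm, post-alignment), `rms_identity`,
#'   `overlap` (fraction of epoch-B points within `overlap_tol` of a
#'   transformed epoch-A point), `R`, `t`.
#' @export
align_epochs <- function(epoch_a, epoch_b, overlap_tol = 0.05,
                         max_icp_iter = 25) {
  a <- as_pos_matrix(epoch_a)
  b <- as_pos_matrix(epoch_b)
  if (nrow(a) < 3 || nrow(b) < 3) stop("each epoch needs >= 3 points")
  if (qr(sweep(a, 2, colMeans(a)))$rank < 2) {
    stop("degenerate geometry: epoch A points are collinear")
  }
  paired <- nrow(a) == nrow(b)
  if (paired) {
    fit <- kabsch(a, b)
  } else {
    # iterated closest-point matching, initialized by centroid alignment
    fit <- list(R = diag(3), t = colMeans(b) - colMeans(a))
    for (it in seq_len(max_icp_iter)) {
      ta <- sweep(a %*% t(fit$R), 2, fit$t, `+`)
      nn <- nearest_index(b, ta)
      new_fit <- kabsch(a, b[nn, , drop = FALSE])
      if (max(abs(new_fit$R - fit$R)) < 1e-10 &&
          max(abs(new_fit$t - fit$t)) < 1e-10) {
        fit <- new_fit
        break
      }
      fit <- new_fit
    }
  }
  ta <- sweep(a %*% t(fit$R), 2, fit$t, `+`)
  rms <- if (paired) sqrt(mean(rowSums((ta - b)^2))) else
    sqrt(mean(rowSums((b - ta[nearest_index(b, ta), , drop = FALSE])^2)))
  rms_id <- if (paired) sqrt(mean(rowSums((a - b)^2))) else
    sqrt(mean(rowSums((b - a[nearest_index(b, a), , drop = FALSE])^2)))
  d_nn <- sqrt(rowSums((b - ta[nearest_index(b, ta), , drop = FALSE])^2))
  theta <- atan2(-fit$R[1, 2], fit$R[1, 1])
  phi <- atan2(-fit$R[2, 3], fit$R[3, 3])
  structure(
    list(
      translation = fit$t,
      rotation_deg = c(theta_z = theta * 180 / pi, phi_x = phi * 180 / pi),
      rms = rms, rms_identity = rms_id,
      overlap = mean(d_nn <= overlap_tol),
      R = fit$R, t = fit$t, paired = paired
    ),
    class = "spt_alignment"
  )
}

#' @export
print.spt_alignment <- function(x, ...) {
  cat(sprintf(
    "Rigid alignment: |t| = %.0f nm, theta_z = %.1f deg, phi_x = %.1f deg, RMS %.1f -> %.1f nm, overlap %.2f\n",
    1000 * sqrt(sum(x$translation^2)), x$rotation_deg[1], x$rotation_deg[2],
    1000 * x$rms_identity, 1000 * x$rms, x$overlap))
  invisible(x)
}

as_pos_matrix <- function(x) {
  if (is.data.frame(x)) {
    cbind(x$x, x$y, if ("z" %in% names(x)) x$z else 0)
  } else {
    m <- as.matrix(x)
    if (ncol(m) == 2) m <- cbind(m, 0)
    m
  }
}

nearest_index <- function(query, ref) {
  vapply(seq_len(nrow(query)), function(i) {
    which.min((ref[, 1] - query[i, 1])^2 + (ref[, 2] - query[i, 2])^2 +
                (ref[, 3] - query[i, 3])^2)
  }, integer(1))
}
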