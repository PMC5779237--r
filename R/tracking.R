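# Frame-to-frame track linking. Each consecutive-frame association is the
# globally optimal (minimum total squared displacement) assignment under the
# displacement gate, solved with the O(n^3) Hungarian algorithm; unmatched
# detections start new tracks and unmatched tracks end, at a cost equal to
# the squared gate.

# Hungarian algorithm (Kuhn-Munkres with potentials) for a square cost
# matrix; returns the column assigned to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0) return(integer())
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(n + 1)        # index j+1 for column j, column 0 is virtual
  p <- integer(n + 1)        # p[j+1]: row matched to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- -1
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1]] <- j
  assignment
}

# optimal gated matching between two point sets; returns for each row of a
# the matched row of b or NA. gate may be a vector (per row of a).
match_points <- function(a, b, gate) {
  na <- nrow(a)
  nb <- nrow(b)
  if (na == 0 || nb == 0) return(rep(NA_integer_, na))
  gate <- rep_len(gate, na)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  big <- (na + nb) * max(gate)^2 + 1
  n <- na + nb
  cost <- matrix(big, n, n)
  ok <- d2 <= matrix(gate^2, na, nb)
  cost[1:na, 1:nb][ok] <- d2[ok]
  for (i in seq_len(na)) cost[i, nb + i] <- gate[i]^2   # track ends
  for (j in seq_len(nb)) cost[na + j, j] <- max(gate)^2 # new track
  cost[(na + 1):n, (nb + 1):n] <- 0
  assign <- solve_assignment(cost)
  out <- assign[seq_len(na)]
  out[out > nb] <- NA_integer_
  # drop any gated-out link (only reachable through the big sentinel cost)
  hit <- which(!is.na(out))
  bad <- hit[d2[cbind(hit, out[hit])] > gate[hit]^2]
  out[bad] <- NA_integer_
  out
}

#' Link localizations into trajectories
#'
#' Processes frames in order; between successive frames the association of
#' existing track heads to new localizations minimizes the total squared
#' displacement subject to the per-step displacement gate
#' (`max_displacement`, scaled by the gap length when gap closing is
#' enabled). Localizations left unmatched start new tracks. Tracks shorter
#' than `min_track_length` are discarded and counted. Uses 3D Euclidean
#' distance when a finite `z` column is present, 2D otherwise.
#'
#' @param localizations `data.frame` with `frame`, `x`, `y` and optionally
#'   `z`.
#' @param params an [link_params()] object.
#' @return A list of class `spt_tracks`: `tracks` (long `data.frame` with
#'   `track`, `frame`, `x`, `y`, `z`), `n_discarded` (tracks below the
#'   length cutoff), `n_localizations_discarded`, `dimensionality`.
#' @export
link <- function(localizations, params = link_params()) {
  stopifnot(all(c("frame", "x", "y") %in% names(localizations)))
  has_z <- "z" %in% names(localizations) && !all(is.na(localizations$z))
  loc <- localizations[order(localizations$frame), , drop = FALSE]
  if (!has_z) loc$z <- 0
  key <- paste(loc$frame, signif(loc$x, 12), signif(loc$y, 12),
               signif(loc$z, 12))
  if (anyDuplicated(key)) {
    warning("duplicate (frame, position) records removed")
    loc <- loc[!duplicated(key), , drop = FALSE]
  }
  frames <- sort(unique(loc$frame))
  by_frame <- split(seq_len(nrow(loc)), loc$frame)
  track_of <- integer(nrow(loc))
  # active tracks: last localization row index and last frame
  active_row <- integer()
  active_frame <- integer()
  active_id <- integer()
  next_id <- 1L
  for (f in frames) {
    idx <- by_frame[[as.character(f)]]
    pts <- as.matrix(loc[idx, c("x", "y", "z")])
    keep <- active_frame >= f - 1 - params$max_gap_frames & active_frame < f
    cand_rows <- active_row[keep]
    if (length(cand_rows)) {
      gaps <- f - active_frame[keep]
      gate <- params$max_displacement * gaps
      heads <- as.matrix(loc[cand_rows, c("x", "y", "z"), drop = FALSE])
      m <- match_points(heads, pts, gate)
    } else {
      m <- integer()
    }
    ids <- integer(length(idx))
    if (length(m)) {
      hit <- !is.na(m)
      ids[m[hit]] <- active_id[keep][hit]
      sel <- which(keep)[hit]
      active_row[sel] <- idx[m[hit]]
      active_frame[sel] <- f
    }
    new_pts <- which(ids == 0L)
    if (length(new_pts)) {
      new_ids <- seq.int(next_id, length.out = length(new_pts))
      ids[new_pts] <- new_ids
      next_id <- next_id + length(new_pts)
      active_row <- c(active_row, idx[new_pts])
      active_frame <- c(active_frame, rep(f, length(new_pts)))
      active_id <- c(active_id, new_ids)
    }
    track_of[idx] <- ids
  }
  loc$track <- track_of
  counts <- table(track_of)
  good <- as.integer(names(counts))[counts >= params$min_track_length]
  n_discarded <- length(counts) - length(good)
  kept <- loc$track %in% good
  out <- loc[kept, c("track", "frame", "x", "y", "z")]
  # renumber retained tracks consecutively
  out$track <- match(out$track, sort(unique(out$track)))
  out <- out[order(out$track, out$frame), ]
  rownames(out) <- NULL
  structure(
    list(tracks = out, n_discarded = n_discarded,
         n_localizations_discarded = sum(!kept),
         dimensionality = if (has_z) 3L else 2L),
    class = "spt_tracks"
  )
}

#' @export
print.spt_tracks <- function(x, ...) {
  cat("Linked", length(unique(x$tracks$track)), "tracks (",
      x$dimensionality, "D );", x$n_discarded,
      "short tracks discarded (", x$n_localizations_discarded,
      "localizations )\n")
  invisible(x)
}
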