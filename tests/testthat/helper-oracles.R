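# Independent brute-force oracles used to check the package implementations.

# all-pairs time-averaged MSD, written as the literal double loop
brute_msd <- function(traj, frame_interval = 1) {
  traj <- traj[order(traj$frame), ]
  pos <- cbind(traj$x, traj$y, if ("z" %in% names(traj)) traj$z else 0)
  fr <- traj$frame
  max_lag <- max(fr) - min(fr)
  out <- data.frame(lag = 0:max_lag, tau = (0:max_lag) * frame_interval,
                    msd = NA_real_, count = 0L)
  out$msd[1] <- 0
  out$count[1] <- nrow(traj)
  for (k in seq_len(max_lag)) {
    vals <- c()
    for (i in seq_len(nrow(traj))) {
      j <- which(fr == fr[i] + k)
      if (length(j) == 1) {
        vals <- c(vals, sum((pos[j, ] - pos[i, ])^2))
      }
    }
    if (length(vals)) {
      out$msd[k + 1] <- mean(vals)
      out$count[k + 1] <- length(vals)
    }
  }
  out
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# exhaustive minimum-total-cost assignment for a square matrix
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- all_permutations(n)
  totals <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  list(assignment = perms[which.min(totals), ], cost = min(totals))
}

# brute-force neighbor count within eps (density-clustering core test)
brute_neighbor_counts <- function(pos, eps) {
  n <- nrow(pos)
  vapply(seq_len(n), function(i) {
    sum(sqrt(rowSums(sweep(pos, 2, pos[i, ])^2)) <= eps)
  }, numeric(1))
}

# closed-form rigid superposition by dense search over in-plane rotations
# (z-rotation only geometry), used on tiny point sets
brute_rigid_2d <- function(a, b, grid_deg = seq(-180, 179.5, by = 0.05)) {
  best <- NULL
  for (th in grid_deg * pi / 180) {
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    ta <- a %*% t(R)
    t0 <- colMeans(b) - colMeans(ta)
    rms <- sqrt(mean(rowSums((sweep(ta, 2, -t0) - b)^2)))
    if (is.null(best) || rms < best$rms) {
      best <- list(theta_deg = th * 180 / pi, t = t0, rms = rms)
    }
  }
  best
}
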