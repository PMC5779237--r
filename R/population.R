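# Population-level mobility analysis: 2D log-log heat maps of diffusion
# coefficient vs trajectory range, 1D Gaussian deconvolution of the
# marginals by EM, and threshold classification into slow/constrained
# fractions.

#' 2D mobility heat map
#'
#' Histogram of log10 trajectory range (columns) against log10 diffusion
#' coefficient (rows). Tracks with zero or flagged diffusion coefficients
#' are excluded from the map and counted; values outside the extents are
#' clipped into the edge bins so counts are conserved.
#'
#' @param metrics an [compute_metrics()] table.
#' @param bin_width bin width in decades (both axes, default 0.1).
#' @param range_extent,d_extent axis extents in log10 units.
#' @return An object of class `spt_heatmap`: `counts` matrix (rows = log10
#'   D bins, cols = log10 range bins), `range_breaks`, `d_breaks`,
#'   `n_dropped`, `n_clipped`.
#' @export
mobility_heatmap <- function(metrics, bin_width = 0.1,
                             range_extent = c(-1.5, 1),
                             d_extent = c(-4, 0)) {
  stopifnot(nrow(metrics) > 0)
  if (diff(range_extent) <= 0 || diff(d_extent) <= 0) {
    stop("zero-width extent")
  }
  ok <- !is.na(metrics$log10_d) & !metrics$d_flagged &
    metrics$trajectory_range > 0
  n_dropped <- sum(!ok)
  lr <- log10(metrics$trajectory_range[ok])
  ld <- metrics$log10_d[ok]
  rb <- seq(range_extent[1], range_extent[2], by = bin_width)
  db <- seq(d_extent[1], d_extent[2], by = bin_width)
  n_clipped <- sum(lr < rb[1] | lr > rb[length(rb)] |
                     ld < db[1] | ld > db[length(db)])
  lr <- pmin(pmax(lr, rb[1]), rb[length(rb)])
  ld <- pmin(pmax(ld, db[1]), db[length(db)])
  ri <- pmin(findInterval(lr, rb, rightmost.closed = TRUE), length(rb) - 1)
  di <- pmin(findInterval(ld, db, rightmost.closed = TRUE), length(db) - 1)
  counts <- matrix(0L, length(db) - 1, length(rb) - 1)
  for (i in seq_along(ri)) {
    counts[di[i], ri[i]] <- counts[di[i], ri[i]] + 1L
  }
  structure(
    list(counts = counts, range_breaks = rb, d_breaks = db,
         n_dropped = n_dropped, n_clipped = n_clipped),
    class = "spt_heatmap"
  )
}

#' @export
plot.spt_heatmap <- function(x, ...) {
  image(x$range_breaks, x$d_breaks, t(x$counts),
        xlab = "log10 trajectory range (um)",
        ylab = "log10 D (um^2/s)", col = hcl.colors(64, "YlOrRd", rev = TRUE),
        ...)
  abline(h = -1.75, v = -0.1, lty = 3, col = "white")
  invisible(x)
}

em_gmm_1d <- function(x, mu, sigma, w, tol, max_iter, sd_floor) {
  n <- length(x)
  k <- length(mu)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r <- dens / tot
    nk <- pmax(colSums(r), 1e-10)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sigma <- sqrt(pmax(
      colSums(r * (outer(x, mu, `-`))^2) / nk, sd_floor^2))
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(w = w, mu = mu, sigma = sigma, loglik = ll, converged = converged,
       n_iter = iter)
}

#' Deconvolve a 1D log-scale metric distribution into Gaussian components
#'
#' Maximum-likelihood Gaussian mixture fit by EM, best of `n_starts`
#' k-means-initialized restarts, deterministic given the seed. Intended for
#' log10 diffusion coefficients or log10 trajectory ranges, where the
#' mobility populations appear as Gaussian peaks.
#'
#' @param values numeric vector (log10 units); non-finite entries are
#'   dropped and counted.
#' @param k number of components (default 2).
#' @param n_starts number of EM restarts (default 10).
#' @param seed integer seed.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @return An object of class `spt_mixture`: `weights`, `means`, `sds`
#'   (components sorted by increasing mean), `loglik`, `converged`, `n`,
#'   `n_dropped`, `effective_k` (components with weight >= 0.02 and
#'   separated means).
#' @export
fit_mixture_1d <- function(values, k = 2, n_starts = 10, seed = 1,
                           tol = 1e-8, max_iter = 1000) {
  x <- values[is.finite(values)]
  n_dropped <- length(values) - length(x)
  n <- length(x)
  if (n < 10 * k) stop("need at least ", 10 * k, " finite values for k = ", k)
  if (stats::sd(x) == 0) stop("degenerate data: all values identical")
  sd_floor <- 1e-3 * stats::sd(x)
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- with_seed(derive_seed(seed, paste0("mixture-start-", s)), {
      km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 1))
      mu <- as.vector(km$centers)
      sig <- vapply(seq_len(k), function(j) {
        v <- x[km$cluster == j]
        max(stats::sd(v), sd_floor, na.rm = TRUE)
      }, numeric(1))
      sig[!is.finite(sig)] <- stats::sd(x)
      list(mu = mu, sigma = sig, w = tabulate(km$cluster, k) / n)
    })
    fit <- em_gmm_1d(x, init$mu, init$sigma, init$w, tol, max_iter, sd_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$mu)
  w <- best$w[ord]; mu <- best$mu[ord]; sig <- best$sigma[ord]
  # effective components: non-negligible weight and separated means
  live <- which(w >= 0.02)
  eff <- 0L
  last_mu <- -Inf
  last_sig <- 0
  for (j in live) {
    if (mu[j] - last_mu > max(sig[j], last_sig)) eff <- eff + 1L
    last_mu <- mu[j]
    last_sig <- sig[j]
  }
  structure(
    list(weights = w, means = mu, sds = sig, loglik = best$loglik,
         converged = best$converged, n = n, n_dropped = n_dropped,
         effective_k = eff, k = k),
    class = "spt_mixture"
  )
}

#' @export
print.spt_mixture <- function(x, digits = 3, ...) {
  cat("Gaussian mixture (", x$k, "components fitted,", x$effective_k,
      "effective ) on", x$n, "values\n")
  tab <- data.frame(weight = round(x$weights, digits),
                    mean = round(x$means, digits),
                    sd = round(x$sds, digits))
  print(tab, row.names = FALSE)
  cat("log-likelihood:", format(x$loglik, digits = 6),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  invisible(x)
}

#' Weight of the fastest (highest-mean) mixture component
#'
#' @param fit an [fit_mixture_1d()] object.
#' @return The weight of the component with the largest mean.
#' @export
mixture_fast_weight <- function(fit) {
  stopifnot(inherits(fit, "spt_mixture"))
  fit$weights[length(fit$weights)]
}

#' Classify tracks into slow / constrained fractions
#'
#' Slow: diffusion coefficient at or below the slow cutoff (default
#' 10^-1.75 = 0.018 µm²/s). Constrained: trajectory range at or below the
#' constrained cutoff (default 10^-0.1 = 0.79 µm). The joint fraction
#' (slow and constrained, the lower-left box of the heat map) is also
#' reported.
#'
#' @param metrics an [compute_metrics()] table.
#' @param thresholds an [classifier_thresholds()] object.
#' @return A list of class `spt_fractions`: `slow`, `constrained`,
#'   `slow_and_constrained` (fractions in [0, 1]), plus counts and `n`.
#' @export
classify_fractions <- function(metrics, thresholds = classifier_thresholds()) {
  stopifnot(nrow(metrics) > 0)
  slow <- metrics$d_coeff <= thresholds$slow_d
  constrained <- metrics$trajectory_range <= thresholds$constrained_range
  structure(
    list(
      slow = mean(slow),
      constrained = mean(constrained),
      slow_and_constrained = mean(slow & constrained),
      n_slow = sum(slow), n_constrained = sum(constrained),
      n = nrow(metrics), thresholds = thresholds
    ),
    class = "spt_fractions"
  )
}

#' @export
print.spt_fractions <- function(x, ...) {
  cat(sprintf(
    "n = %d tracks: %.1f%% slow (D <= %.3f um^2/s), %.1f%% constrained (range <= %.2f um), %.1f%% both\n",
    x$n, 100 * x$slow, x$thresholds$slow_d, 100 * x$constrained,
    x$thresholds$constrained_range, 100 * x$slow_and_constrained))
  invisible(x)
}
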