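# Configuration-driven end-to-end pipeline and table I/O. Localization and
# trajectory tables are plain column-named CSV with a '# units:' comment
# header, so files round-trip losslessly and units are explicit.

#' Read a localization table
#'
#' Column-named CSV with mandatory `frame`, `x`, `y` columns; `z`,
#' `channel`, `intensity` etc. are carried through. A leading comment line
#' `# units: nm` (or `um`) declares the length unit; positions are
#' normalized to µm. Missing `z` sets a 2D-mode attribute.
#'
#' @param path file path.
#' @param units unit override when the file has no unit header
#'   (default "um").
#' @return `data.frame` in µm with attributes `units_in` and `mode_2d`.
#' @export
read_localizations <- function(path, units = NULL) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1)
  file_units <- NULL
  if (grepl("^#\\s*units:", first)) {
    file_units <- trimws(sub("^#\\s*units:", "", first))
  }
  if (!is.null(file_units) && !is.null(units) && file_units != units) {
    stop("mixed units: file declares '", file_units,
         "' but '", units, "' was requested")
  }
  units <- if (!is.null(file_units)) file_units else
    if (!is.null(units)) units else "um"
  if (!units %in% c("um", "nm")) stop("unknown unit '", units, "'")
  tab <- utils::read.csv(path, comment.char = "#")
  missing_cols <- setdiff(c("frame", "x", "y"), names(tab))
  if (length(missing_cols)) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  }
  scale <- if (units == "nm") 1e-3 else 1
  for (col in intersect(c("x", "y", "z"), names(tab))) {
    tab[[col]] <- tab[[col]] * scale
  }
  attr(tab, "units_in") <- units
  attr(tab, "mode_2d") <- !"z" %in% names(tab)
  tab
}

#' @rdname read_localizations
#' @param localizations table to write (µm).
#' @export
write_localizations <- function(localizations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: um", con)
  utils::write.csv(localizations, con, row.names = FALSE)
  invisible(path)
}

#' Write / read trajectory tables
#'
#' Long-format CSV (`track`, `frame`, `x`, `y`, `z`, µm) with a unit header
#' and a footer comment recording the track count; `read_trajectories` is
#' the exact inverse.
#'
#' @param tracks long `data.frame` or `spt_tracks` object.
#' @param path file path.
#' @return `write_trajectories` returns the path; `read_trajectories` the
#'   table with attribute `n_tracks_footer`.
#' @export
write_trajectories <- function(tracks, path) {
  if (inherits(tracks, "spt_tracks")) tracks <- tracks$tracks
  stopifnot(all(c("track", "frame", "x", "y") %in% names(tracks)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: um", con)
  utils::write.csv(tracks, con, row.names = FALSE)
  writeLines(paste0("# n_tracks: ", length(unique(tracks$track))), con)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  footer <- grep("^#\\s*n_tracks:", lines, value = TRUE)
  tab <- utils::read.csv(text = lines, comment.char = "#")
  attr(tab, "n_tracks_footer") <- if (length(footer)) {
    as.integer(trimws(sub("^#\\s*n_tracks:", "", footer[1])))
  } else NA_integer_
  tab
}

#' Pipeline configuration
#'
#' Bundles every knob of an end-to-end run: the probe preset, scene
#' geometry, acquisition parameters, classifier thresholds, the synaptic
#' rule, linking parameters, stage toggles and the seed. Serializes
#' losslessly to JSON via [write_config()] / [read_config()].
#'
#' @param preset preset name (see [population_presets()]).
#' @param n_tracks number of simulated tracks.
#' @param n_psd number of PSDs in the scene.
#' @param field_size field extent (µm, length-3).
#' @param frame_interval s.
#' @param n_frames frames per track.
#' @param localization_noise per-axis noise sd (µm, length-3).
#' @param thresholds [classifier_thresholds()].
#' @param rule [synaptic_rule()].
#' @param linking [link_params()].
#' @param simulate_drift add (and then correct) a smooth stage drift.
#' @param relink re-link localizations from scratch instead of keeping the
#'   simulator's track identities. Frame-by-frame linking is only
#'   well-posed at low particle density, so this defaults to `FALSE` for
#'   dense populations.
#' @param locs_per_cluster,background_density PALM table parameters.
#' @param seed integer seed for the whole run.
#' @return An object of class `spt_config`.
#' @export
pipeline_config <- function(preset = "sqd_sa",
                            n_tracks = 1000,
                            n_psd = 20,
                            field_size = c(20, 20, 1),
                            frame_interval = 0.05,
                            n_frames = 600,
                            localization_noise = c(0.0096, 0.0082, 0.018),
                            thresholds = classifier_thresholds(),
                            rule = synaptic_rule(),
                            linking = link_params(),
                            simulate_drift = FALSE,
                            relink = FALSE,
                            locs_per_cluster = 400,
                            background_density = 2,
                            seed = 1) {
  structure(
    list(preset = preset, n_tracks = n_tracks, n_psd = n_psd,
         field_size = field_size, frame_interval = frame_interval,
         n_frames = n_frames, localization_noise = localization_noise,
         thresholds = unclass(thresholds)[c("slow_log10_d",
                                            "constrained_log10_range")],
         rule = unclass(rule),
         linking = unclass(linking),
         simulate_drift = simulate_drift, relink = relink,
         locs_per_cluster = locs_per_cluster,
         background_density = background_density,
         seed = seed),
    class = "spt_config"
  )
}

#' @rdname pipeline_config
#' @param config an `spt_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "spt_config")
}

smooth_drift_fun <- function(amplitude, duration, seed) {
  # sum of low-frequency sinusoids plus a linear component, per axis
  with_seed(derive_seed(seed, "drift-model"), {
    par <- lapply(1:3, function(ax) {
      list(a = rnorm(2, sd = amplitude / 2),
           ph = runif(2, 0, 2 * pi),
           fr = runif(2, 0.5, 1.5) / duration,
           lin = rnorm(1, sd = amplitude / duration))
    })
    function(t) {
      vapply(par, function(p) {
        sum(p$a * sin(2 * pi * p$fr * t + p$ph)) + p$lin * t
      }, numeric(1))
    }
  })
}

#' Run the full analysis pipeline on a simulated scene
#'
#' Generates a scene and a track population from the configured preset,
#' simulates the Homer PALM table, optionally injects and corrects stage
#' drift, optionally re-links localizations, computes per-track mobility
#' metrics, deconvolves the log10 D and log10 range marginals, classifies
#' slow/constrained fractions and synaptic membership, and returns a run
#' report reconciling counts across stages. Fully deterministic given the
#' config seed.
#'
#' @param config an [pipeline_config()] object.
#' @return An object of class `spt_report`; see `print` output for the
#'   summary tables.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "spt_config"))
  acq <- acquisition_params(config$frame_interval, config$n_frames,
                            config$field_size, config$localization_noise)
  thresholds <- classifier_thresholds(config$thresholds$slow_log10_d,
                                      config$thresholds$constrained_log10_range)
  rule <- synaptic_rule(config$rule$candidate_radius,
                        config$rule$mean_distance_threshold)
  linking <- link_params(config$linking$max_displacement,
                         config$linking$max_gap_frames,
                         config$linking$min_track_length)
  counts <- list()

  scene <- make_scene(config$n_psd, config$field_size, seed = config$seed)
  pop <- simulate_population(config$preset, scene, config$n_tracks, acq,
                             seed = config$seed)
  palm <- simulate_homer_palm(scene, config$locs_per_cluster,
                              background_density = config$background_density,
                              seed = config$seed)
  counts$track_localizations_in <- nrow(pop$tracks)
  counts$palm_localizations_in <- nrow(palm)

  track_tab <- pop$tracks
  drift_error <- NULL
  if (isTRUE(config$simulate_drift)) {
    duration <- config$n_frames * config$frame_interval
    drift_fun <- smooth_drift_fun(0.1, duration, config$seed)
    times <- (seq_len(config$n_frames) - 1) * config$frame_interval
    drift_mat <- t(vapply(times, drift_fun, numeric(3)))
    fid <- simulate_fiducials(drift_mat, n_fiducials = 25, noise = 0.005,
                              acq = acq, seed = config$seed)
    est <- estimate_drift(fid, smoothing_window = 10)
    idx <- match(track_tab$frame, seq_len(config$n_frames))
    track_tab$x <- track_tab$x + drift_mat[idx, 1]
    track_tab$y <- track_tab$y + drift_mat[idx, 2]
    track_tab$z <- track_tab$z + drift_mat[idx, 3]
    track_tab <- apply_drift_correction(track_tab, est)
    rel <- sweep(drift_mat, 2, drift_mat[1, ])
    drift_error <- sqrt(mean((est$dx - rel[, 1])^2 + (est$dy - rel[, 2])^2))
  }

  if (isTRUE(config$relink)) {
    linked <- link(track_tab[, c("frame", "x", "y", "z")], linking)
    tracks <- linked$tracks
    counts$tracks_retained <- length(unique(tracks$track))
    counts$tracks_discarded <- linked$n_discarded
    counts$localizations_discarded <- linked$n_localizations_discarded
  } else {
    tracks <- track_tab
    counts$tracks_retained <- length(unique(tracks$track))
    counts$tracks_discarded <- 0L
    counts$localizations_discarded <- 0L
  }

  metrics <- compute_metrics(tracks, config$frame_interval)
  counts$tracks_with_metrics <- nrow(metrics)

  clusters <- cluster_palm(palm)
  counts$psd_clusters <- nrow(clusters$clusters)

  fractions <- classify_fractions(metrics, thresholds)
  mix_d <- tryCatch(
    fit_mixture_1d(metrics$log10_d, k = 2, seed = config$seed),
    error = function(e) NULL)
  mix_range <- tryCatch(
    fit_mixture_1d(log10(metrics$trajectory_range[
      metrics$trajectory_range > 0]), k = 2, seed = config$seed),
    error = function(e) NULL)
  syn <- classify_synaptic(tracks, clusters, rule)
  dist_fr <- distance_fractions(tracks, clusters)

  structure(
    list(
      config = config,
      counts = counts,
      scene = scene,
      metrics = metrics,
      clusters = clusters,
      fractions = fractions,
      mixture_log10_d = mix_d,
      mixture_log10_range = mix_range,
      synaptic = syn,
      synaptic_fraction = mean(syn$synaptic),
      distance_fractions = dist_fr$fractions,
      drift_residual_um = drift_error,
      truth = pop$truth,
      thresholds = thresholds,
      version = as.character(utils::packageVersion("sptnano"))
    ),
    class = "spt_report"
  )
}

#' @export
print.spt_report <- function(x, ...) {
  cat("== sptnano run report (v", x$version, ", preset ",
      x$config$preset, ", seed ", x$config$seed, ") ==\n", sep = "")
  cat("PSDs:", nrow(x$scene$psd_centers),
      "| clusters found:", x$counts$psd_clusters, "\n")
  cat("tracks:", x$counts$tracks_retained, "retained,",
      x$counts$tracks_discarded, "discarded;",
      x$counts$tracks_with_metrics, "with metrics\n")
  print(x$fractions)
  cat(sprintf("synaptic fraction: %.1f%%\n", 100 * x$synaptic_fraction))
  for (nm in names(x$distance_fractions)) {
    cat(sprintf("  %s of Homer center: %.1f%%\n", nm,
                100 * x$distance_fractions[[nm]]))
  }
  if (!is.null(x$mixture_log10_d)) {
    cat(sprintf("log10 D mixture: fast weight %.1f%% at mean %.2f\n",
                100 * mixture_fast_weight(x$mixture_log10_d),
                x$mixture_log10_d$means[length(x$mixture_log10_d$means)]))
  }
  if (!is.null(x$drift_residual_um)) {
    cat(sprintf("drift correction residual: %.2f nm\n",
                1000 * x$drift_residual_um))
  }
  invisible(x)
}
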