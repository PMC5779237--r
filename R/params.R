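#' Acquisition parameters
#'
#' Frame timing, field geometry and per-axis localization precision of the
#' simulated acquisition. Defaults follow a quantum-dot tracking movie:
#' 50 ms frames, 30 s epochs (600 frames), and per-axis localization noise of
#' 9.6 nm (x), 8.2 nm (y) and 18 nm (z).
#'
#' @param frame_interval frame interval in seconds (> 0).
#' @param n_frames number of frames per track (>= 2).
#' @param field_size field extent per axis in µm (length-3).
#' @param localization_noise per-axis localization noise sd in µm (length-3,
#'   all >= 0).
#' @return An object of class `spt_acquisition` (a list of the four fields).
#' @examples
#' acq <- acquisition_params(n_frames = 100)
#' acq$frame_interval
#' @export
acquisition_params <- function(frame_interval = 0.05,
                               n_frames = 600,
                               field_size = c(20, 20, 1),
                               localization_noise = c(0.0096, 0.0082, 0.018)) {
  stopifnot(
    is.numeric(frame_interval), length(frame_interval) == 1, frame_interval > 0,
    is.numeric(n_frames), length(n_frames) == 1, n_frames >= 2,
    is.numeric(field_size), length(field_size) == 3, all(field_size > 0),
    is.numeric(localization_noise), length(localization_noise) == 3,
    all(localization_noise >= 0)
  )
  structure(
    list(
      frame_interval = frame_interval,
      n_frames = as.integer(n_frames),
      field_size = field_size,
      localization_noise = localization_noise
    ),
    class = "spt_acquisition"
  )
}

preset_table_path <- function() {
  system.file("extdata", "presets.json", package = "sptnano", mustWork = TRUE)
}

preset_env <- new.env(parent = emptyenv())

load_preset_table <- function() {
  if (is.null(preset_env$table)) {
    preset_env$table <- jsonlite::read_json(preset_table_path(), simplifyVector = TRUE)
  }
  preset_env$table
}

#' Named per-probe population presets
#'
#' Each preset encodes the mobility mixture measured for one probe/linker
#' combination: the fraction of fast freely-diffusing tracks, the fraction
#' attached to PSD nanodomains (synaptic), log10 diffusion-coefficient means
#' and spreads for both populations, trajectory-range distributions, and the
#' placement of extrasynaptic tracks relative to PSD centers. Values are
#' loaded from a versioned JSON table shipped with the package.
#'
#' @param name preset name; one of the names returned by
#'   `population_presets()`.
#' @return An object of class `spt_preset`: a list with fields
#'   `name`, `fraction_fast`, `synaptic_fraction`, `d_fast_log10`,
#'   `d_slow_log10`, `sd_fast`, `sd_slow`, `nanodomain_radius`,
#'   `range_fast_um`, `range_fast_sd`, `range_slow_um`, `range_slow_sd`,
#'   `extrasyn_dist_um`.
#' @examples
#' p <- population_preset("sqd_sa")
#' p$synaptic_fraction
#' @export
population_preset <- function(name) {
  tab <- load_preset_table()
  if (!name %in% names(tab$presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(tab$presets), collapse = ", "))
  }
  p <- tab$presets[[name]]
  p$name <- name
  stopifnot(
    p$fraction_fast >= 0, p$fraction_fast <= 1,
    p$synaptic_fraction >= 0, p$synaptic_fraction <= 1,
    p$fraction_fast + p$synaptic_fraction <= 1 + 1e-12,
    p$nanodomain_radius > 0, p$sd_fast > 0, p$sd_slow > 0,
    p$range_fast_um > 0, p$range_slow_um > 0
  )
  structure(p, class = "spt_preset")
}

#' @rdname population_preset
#' @export
population_presets <- function() names(load_preset_table()$presets)

#' Mobility classifier thresholds
#'
#' The semi-quantitative cutoffs separating slow from fast and constrained
#' from mobile tracks: slow means D at or below 10^-1.75 (0.018) µm²/s and
#' constrained means a trajectory range at or below 10^-0.1 (0.79) µm.
#'
#' @param slow_log10_d log10 diffusion-coefficient cutoff (log10 µm²/s).
#' @param constrained_log10_range log10 trajectory-range cutoff (log10 µm).
#' @return An object of class `spt_thresholds` with the two cutoffs in both
#'   log10 and linear units.
#' @examples
#' th <- classifier_thresholds()
#' th$slow_d       # 0.0178 um^2/s
#' th$constrained_range  # 0.794 um
#' @export
classifier_thresholds <- function(slow_log10_d = -1.75,
                                  constrained_log10_range = -0.1) {
  structure(
    list(
      slow_log10_d = slow_log10_d,
      constrained_log10_range = constrained_log10_range,
      slow_d = 10^slow_log10_d,
      constrained_range = 10^constrained_log10_range
    ),
    class = "spt_thresholds"
  )
}

#' Synaptic classification rule
#'
#' A trajectory is a candidate for a synapse if it passes within
#' `candidate_radius` of that synapse's center; it is called synaptic when
#' the average distance of all its points to the nearest candidate center is
#' below `mean_distance_threshold`.
#'
#' @param candidate_radius candidate search radius in µm (default 2).
#' @param mean_distance_threshold mean-distance cutoff in µm (default 0.55).
#' @return An object of class `spt_synaptic_rule`.
#' @export
synaptic_rule <- function(candidate_radius = 2.0,
                          mean_distance_threshold = 0.55) {
  stopifnot(candidate_radius > 0, mean_distance_threshold > 0)
  structure(
    list(
      candidate_radius = candidate_radius,
      mean_distance_threshold = mean_distance_threshold
    ),
    class = "spt_synaptic_rule"
  )
}

#' Track linking parameters
#'
#' @param max_displacement maximum displacement per frame step in µm
#'   (default 1, the single-step gate for quantum-dot tracking).
#' @param max_gap_frames maximum number of skipped frames bridged when
#'   linking (default 0; the gate scales with the gap length).
#' @param min_track_length minimum number of points for a track to be
#'   retained (default 10).
#' @return An object of class `spt_link_params`.
#' @export
link_params <- function(max_displacement = 1.0,
                        max_gap_frames = 0L,
                        min_track_length = 10L) {
  stopifnot(max_displacement > 0, max_gap_frames >= 0, min_track_length >= 1)
  structure(
    list(
      max_displacement = max_displacement,
      max_gap_frames = as.integer(max_gap_frames),
      min_track_length = as.integer(min_track_length)
    ),
    class = "spt_link_params"
  )
}
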