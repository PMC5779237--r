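{
  "version": "1.0",
  "description": "Per-probe two-population mobility presets for AMPA-receptor tracking simulations. Tracks are drawn from three subpopulations: fast/free (extrasynaptic), confined synaptic (in PSD nanodomains) and confined extrasynaptic. Diffusion coefficients are log10(um^2/s) with per-track log-normal spread; trajectory ranges are um (mean, sd) and set the per-track confinement diameter; extrasyn_dist_um is the uniform range of the distance from an extrasynaptic track centre to its nearest PSD, calibrated so the distance-to-PSD histogram reproduces the reported 75%/91% fractions within 0.5/1.0 um for the small-probe presets.",
  "presets": {
    "bqd_day1": {
      "label": "big quantum dot + streptavidin, day 1 post-transfection",
      "fraction_fast": 0.73,
      "synaptic_fraction": 0.05,
      "d_fast_log10": -1.25,
      "d_slow_log10": -2.5,
      "sd_fast": 0.3,
      "sd_slow": 0.3,
      "nanodomain_radius": 0.1,
      "range_fast_um": 1.3,
      "range_fast_sd": 0.4,
      "range_slow_um": 0.39,
      "range_slow_sd": 0.14,
      "extrasyn_dist_um": [0.55, 1.5]
    },
    "bqd_day3": {
      "label": "big quantum dot + streptavidin, day 3 post-transfection (broader, slower)",
      "fraction_fast": 0.35,
      "synaptic_fraction": 0.05,
      "d_fast_log10": -1.25,
      "d_slow_log10": -2.5,
      "sd_fast": 0.45,
      "sd_slow": 0.45,
      "nanodomain_radius": 0.1,
      "range_fast_um": 1.3,
      "range_fast_sd": 0.5,
      "range_slow_um": 0.39,
      "range_slow_sd": 0.16,
      "extrasyn_dist_um": [0.55, 1.5]
    },
    "sqd_sa": {
      "label": "small quantum dot + streptavidin",
      "fraction_fast": 0.25,
      "synaptic_fraction": 0.75,
      "d_fast_log10": -1.25,
      "d_slow_log10": -2.41,
      "sd_fast": 0.3,
      "sd_slow": 0.3,
      "nanodomain_radius": 0.1,
      "range_fast_um": 1.0,
      "range_fast_sd": 0.3,
      "range_slow_um": 0.418,
      "range_slow_sd": 0.172,
      "extrasyn_dist_um": [0.4, 1.2]
    },
    "sqd_gbp": {
      "label": "small quantum dot + anti-GFP nanobody",
      "fraction_fast": 0.18,
      "synaptic_fraction": 0.82,
      "d_fast_log10": -1.25,
      "d_slow_log10": -2.53,
      "sd_fast": 0.3,
      "sd_slow": 0.3,
      "nanodomain_radius": 0.1,
      "range_fast_um": 1.0,
      "range_fast_sd": 0.3,
      "range_slow_um": 0.42,
      "range_slow_sd": 0.17,
      "extrasyn_dist_um": [0.4, 1.2]
    },
    "sqd_msa": {
      "label": "small quantum dot + monomeric streptavidin",
      "fraction_fast": 0.12,
      "synaptic_fraction": 0.88,
      "d_fast_log10": -1.25,
      "d_slow_log10": -2.59,
      "sd_fast": 0.3,
      "sd_slow": 0.3,
      "nanodomain_radius": 0.1,
      "range_fast_um": 1.0,
      "range_fast_sd": 0.3,
      "range_slow_um": 0.363,
      "range_slow_sd": 0.144,
      "extrasyn_dist_um": [0.4, 1.2]
    },
    "atto647n": {
      "label": "Atto647N organic dye + streptavidin",
      "fraction_fast": 0.23,
      "synaptic_fraction": 0.77,
      "d_fast_log10": -1.25,
      "d_slow_log10": -2.55,
      "sd_fast": 0.3,
      "sd_slow": 0.3,
      "nanodomain_radius": 0.1,
      "range_fast_um": 1.0,
      "range_fast_sd": 0.3,
      "range_slow_um": 0.38,
      "range_slow_sd": 0.156,
      "extrasyn_dist_um": [0.4, 1.2]
    },
    "cf633": {
      "label": "CF633 organic dye + streptavidin",
      "fraction_fast": 0.07,
      "synaptic_fraction": 0.9,
      "d_fast_log10": -1.25,
      "d_slow_log10": -2.7,
      "sd_fast": 0.3,
      "sd_slow": 0.3,
      "nanodomain_radius": 0.1,
      "range_fast_um": 1.0,
      "range_fast_sd": 0.3,
      "range_slow_um": 0.38,
      "range_slow_sd": 0.14,
      "extrasyn_dist_um": [0.4, 1.2]
    },
    "bqd_ecm_removed": {
      "label": "big quantum dot after enzymatic ECM removal (slow population absent)",
      "fraction_fast": 1.0,
      "synaptic_fraction": 0.0,
      "d_fast_log10": -1.2,
      "d_slow_log10": -2.5,
      "sd_fast": 0.3,
      "sd_slow": 0.3,
      "nanodomain_radius": 0.1,
      "range_fast_um": 1.3,
      "range_fast_sd": 0.4,
      "range_slow_um": 0.39,
      "range_slow_sd": 0.14,
      "extrasyn_dist_um": [0.55, 1.5]
    },
    "sqd_ecm_removed": {
      "label": "small quantum dot after enzymatic ECM removal (essentially unchanged)",
      "fraction_fast": 0.25,
      "synaptic_fraction": 0.75,
      "d_fast_log10": -1.25,
      "d_slow_log10": -2.44,
      "sd_fast": 0.3,
      "sd_slow": 0.3,
      "nanodomain_radius": 0.1,
      "range_fast_um": 1.0,
      "range_fast_sd": 0.3,
      "range_slow_um": 0.418,
      "range_slow_sd": 0.172,
      "extrasyn_dist_um": [0.4, 1.2]
    }
  }
}
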