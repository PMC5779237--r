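---
title: "Models and methods behind sptnano"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sptnano}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptnano)
```

This vignette describes the models the package implements, the parameters
that matter and why they take the defaults they do, what the synthetic
generators do and do not emulate, and the numerical choices made where the
underlying methods literature leaves the design open.

## Motion models

Receptor tracks are generated from two motion models:

* **Free diffusion** — unbounded 3D Brownian motion with per-axis increment
  variance `2 D dt` (`simulate_trajectory(kind = "free")`).
* **Confined diffusion** — Brownian motion reflected at the boundary of a
  sphere, the hard-wall picture of a receptor held inside a nanodomain
  (`kind = "confined"`). Reflection was chosen over harmonic tethering
  because it gives a hard, assertable geometric bound: noise-free positions
  never exceed the radius, and the long-time MSD plateaus at
  `(6/5) r^2` (the uniform stationary law in a sphere). Tracks start from
  that stationary law so early lags are representative.

In `simulate_population()` the *fast* subpopulation is also reflected
Brownian motion, but inside a sphere whose diameter is drawn from the
preset's fast trajectory-range distribution (~1.0–1.3 µm). Dendritic
membranes bound receptor excursions in reality; literally unbounded motion
at `D ~ 10^-1.25` µm²/s over 600 frames would produce ~3 µm ranges,
inconsistent with the fast-population range mode the presets encode.
`simulate_trajectory(kind = "free")` remains genuinely unbounded for
estimator calibration.

Confined population tracks draw their confinement diameter from the
preset's slow trajectory-range distribution (mean ~0.36–0.42 µm per
probe), which is broader than the ~200 nm nanodomain itself; the measured
trajectory-range statistic, not the nominal nanodomain size, is what the
analysis reproduces. The scene's nanodomain geometry (radius 0.1 µm,
centers within 0.25 µm of their PSD center, offset magnitude ~150 ± 42 nm)
governs *where* synaptic tracks sit, and hence the distance-to-PSD
histograms.

## Population presets

Each probe preset (`inst/extdata/presets.json`, versioned) encodes three
subpopulations: fast/free extrasynaptic, confined synaptic and confined
extrasynaptic. Fractions, log10 D means (fast ~`-1.25`, slow
`-2.41`…`-2.70` per probe) and range distributions come from the study
conditions the package models; per-track log10 D spread defaults to 0.3
decades, the width of the observed mobility peaks. Extrasynaptic track
centers sit at a uniform distance from their nearest PSD — `U(0.4, 1.2)` µm
for small probes, calibrated analytically so the distance-to-PSD histogram
reproduces the reported 75% / 91% fractions within 0.5 / 1.0 µm given the
0.75 synaptic fraction; `U(0.55, 1.5)` µm for big-probe presets, whose
lower edge encodes the ~0.5 µm Homer distance of the confined
extrasynaptic population. The big-probe day-3 fast fraction is not printed
anywhere, only that it decreases markedly; 0.35 was chosen once as a
plausible value and is not otherwise load-bearing.

## Acquisition and localization

Defaults: 50 ms frames, 600-frame (30 s) epochs, per-axis localization
noise 9.6 / 8.2 / 18 nm (x/y/z), the precision scale of quantum-dot
tracking. The astigmatic PSF uses defocus curves
`w(z) = w0 sqrt(1 + ((z -/+ gamma)/d)^2)` with `w0 = 130` nm (Gaussian
sigma — sigma is the width convention throughout; FWHM = 2.355 sigma at
I/O), `gamma = 250` nm, `d = 400` nm, 100 nm pixels. Spots are rendered by
exact pixel integration (so a noiseless spot sums to its photon count),
with Poisson shot noise and Gaussian read noise.

Spot fitting is Levenberg–Marquardt least squares of a pixel-integrated
elliptical Gaussian; amplitude and widths are parameterized on the log
scale for positivity. Non-converged fits are dropped and counted, never
silently kept. The z lookup minimizes the distance between measured and
calibrated widths in `(sqrt(wx), sqrt(wy))` space — the square-root metric
damps the leverage of the large defocused width — by dense-grid argmin
(1 nm grid) with local parabolic refinement; boundary minima are flagged
out-of-range rather than returned as valid.

## Registration

* **Drift**: each fiducial's displacement from its own time-mean estimates
  the common stage motion; the per-frame **median** across fiducials
  (robust to a misbehaving marker) is smoothed with a 10-frame moving
  average and zeroed at the reference frame. With 25 fiducials and 5 nm
  per-frame noise the residual is a few tenths of a nanometre. Residuals
  are quoted in the mean-zero gauge: a constant offset between estimated
  and true drift translates the entire reconstruction uniformly and is
  unobservable within the image.
* **Chromatic mapping**: per-axis 2D polynomial (default degree 2) fitted
  by least squares on matched nanohole pairs, with the residual always
  evaluated on a held-out 20% split — the quoted 2 nm margin is a
  validation error, and training residuals would understate it. The map is
  fitted at focus and flagged invalid beyond |z| = 400 nm. Nanohole
  `loc_noise` is the 2D RMS localization error per hole per channel
  (per-axis sigma = noise / sqrt(2)).

## Linking

Frames are processed in order; each frame-pair association minimizes the
total squared displacement under the 1 µm single-step gate, solved exactly
with the Hungarian algorithm on a cost matrix augmented with
track-termination and track-birth dummies priced at the squared gate. An
optimal matching was chosen over greedy nearest-neighbor because the
greedy rule is order-dependent and untestable against an oracle; the
package's assignment is verified against exhaustive enumeration. Gap
closing is off by default (blinking probes can enable it; the gate scales
with the gap length). Tracks shorter than 10 frames are discarded and
counted. Note that frame-by-frame linking is only well-posed at low
particle density; `run_pipeline()` therefore keeps the simulator's track
identities unless `relink = TRUE` is set for sparse scenes.

## Diffusion metrics

The time-averaged MSD uses all pairs per lag. D comes from a weighted
(pair-count) least-squares line through the first 4 lags with a **free
intercept**: localization noise adds a constant `2 sum(sigma_axis^2)` to
every MSD point, so an origin-forced fit is biased upward, while the free
intercept leaves the slope unbiased (a property the tests assert at 20 nm
noise). Slope = `6 D` in 3D; a 2D mode (slope = `4 D`) exists for z-free
tables and is recorded. Negative slopes are floored to zero and flagged,
and flagged tracks are excluded from log-scale histograms but counted.

## Population analysis and classification

Deconvolution operates on the 1D marginals (log10 D and log10 range
separately); the 2D heat map (0.1-decade bins, edge-clipped with counts
conserved) is descriptive output. The EM fitter uses k-means
initialization, 10 seeded restarts, relative log-likelihood tolerance
1e-8, and an sd floor of 1e-3 of the data sd to avoid spike collapse. A
fitted pair of components is reported as *effectively one* when a
component's weight falls below 0.02 or adjacent means are separated by
less than the larger component sd. Classifier cutoffs are exactly
`10^-1.75` µm²/s and `10^-0.1` µm and are configurable.

## Synapse analysis

PSDs are found by density-based clustering (0.1 µm neighborhood, 20-point
core rule — chosen because it tolerates the uniform background the PALM
generator produces; no specific algorithm is canonical here). The synaptic
rule is deliberately two-stage: candidate synapses are those the
trajectory passes within 2 µm of, and the *nearest center is fixed per
trajectory* as the one minimizing the trajectory-mean distance — the
per-point alternative reading would let a wandering track switch synapses
mid-trajectory. Synaptic means that mean distance < 0.55 µm. Epoch
alignment is a least-squares rigid transform (Kabsch; scale fixed at 1),
reported as an in-plane rotation about z and an out-of-plane rotation
about x from the decomposition `R = Rx(phi) Rz(theta)`, with an overlap
score counting epoch-B points within 50 nm of the transformed epoch-A
cloud; unpaired point sets go through iterated nearest-neighbor matching.

## What the generators do and do not emulate

The synthetic module reproduces the *statistical* structure of the
experiments: population fractions, mobility scales, confinement geometry,
PALM cluster shape with uniform background, fiducial grids under smooth
drift, and smooth low-order chromatic fields. It does not emulate probe
blinking/photobleaching kinetics, cross-linking by multivalent probes,
dendrite morphology (extrasynaptic placement is distance-based, not
membrane-constrained), PSD shape beyond isotropic Gaussians, or depth- and
background-dependent localization artifacts. Passing tests therefore
demonstrate that the *analysis chain* recovers known ground truth under
the stated conditions — not that those conditions capture every property
of live-neuron data.

## Problem sizes and determinism

Tests and the acceptance script use the epoch length of the study (600
frames at 50 ms) with track counts from 483 (the smallest reported
dataset) to 10^4, averaged over 10–20 seeds where a printed value refers
to a population statistic. Every generator derives its stream from a
single top-level seed via stable text labels, so adding a generator never
perturbs the others and identical configurations are bit-reproducible.

## Known limitations

* The density clustering is O(n·k) with cell lists but single-threaded;
  PALM tables beyond ~10^5 points will be slow.
* The Hungarian linker is exact but O(n^3) per frame pair; it is not meant
  for densely labeled movies (hundreds of simultaneous emitters).
* The chromatic map is fitted at focus only; the z-dependence of real
  aberration fields is handled by flagging, not modeling.
* Mixture deconvolution assumes Gaussian components on the log scale;
  strongly skewed mobility distributions will load the weight estimates.
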