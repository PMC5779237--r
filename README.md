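# sptnano

Single-particle tracking (SPT) analysis of membrane receptors confined in
synaptic nanodomains — an R implementation of the full analysis chain used
to study AMPA-receptor mobility at synapses with 3D super-resolution
microscopy, from synthetic image/localization data through diffusion
metrics, population deconvolution and synaptic classification.

## The scientific problem

Whether AMPA-type glutamate receptors (AMPARs) accumulate in a mobile
extrasynaptic pool or sit confined inside post-synaptic densities (PSDs)
depends strongly on the size of the fluorescent probe used to track them.
Big quantum dots (>20 nm) cannot enter the ~30 nm synaptic cleft and report
mostly fast, far-ranging extrasynaptic motion; small quantum dots (~10 nm)
and organic dyes (~4 nm) report receptors diffusing slowly inside ~200 nm
nanodomains within PSDs. Quantifying this requires a chain of standard SPT
machinery:

1. **3D localization** — astigmatic PSF fitting; the width asymmetry
   (wx, wy) of each spot encodes its z position via a bead-calibrated
   defocus curve.
2. **Registration** — stage drift measured from patterned fiducial markers
   (x/y residual ~1 nm), and chromatic aberration between color channels
   mapped on a nanohole grid (~80 nm raw offset, ≤2 nm after a polynomial
   mapping fitted at focus, valid to |z| ≤ 400 nm).
3. **Track linking** — frame-to-frame assignment with a 1 µm maximum
   single-step displacement.
4. **Per-track mobility metrics** — the diffusion coefficient *D* from a
   weighted line through the first 4 points of the time-averaged MSD curve
   (slope = 6 *D* in 3D, free intercept absorbing localization noise), and
   the *trajectory range* (the maximum over x/y/z of the coordinate span).
5. **Population analysis** — 2D heat maps of log10 *D* vs log10 range;
   1D marginals deconvolved into two Gaussian components by EM; tracks
   classified *slow* when D ≤ 10^-1.75 (0.018) µm²/s and *constrained*
   when range ≤ 10^-0.1 (0.79) µm.
6. **Synaptic classification** — PSDs identified by density-clustering
   Homer1c PALM localizations; a trajectory is *synaptic* when its mean
   distance to the nearest cluster center (among candidates within 2 µm)
   is below 0.55 µm. Nanodomain stability across timed epochs is
   quantified by rigid (translation + rotation) alignment.

Because the raw neuron movies are not deposited, the package ships a
first-class synthetic-scene module that generates every input at the
reported population parameters: two-population trajectory mixtures per
probe preset (`bqd_day1`, `sqd_sa`, `cf633`, ...), Homer1c PALM cluster
tables, fiducial drift traces, chromatic nanohole grids, and rendered
astigmatic frames — so the whole pipeline is testable end to end.

## Worked example

```r
library(sptnano)

acq   <- acquisition_params()                 # 50 ms frames, 600 frames
scene <- make_scene(n_psd = 12, seed = 1)
pop   <- simulate_population("sqd_sa", scene, n_tracks = 2000, acq, seed = 1)

metrics <- compute_metrics(pop, acq$frame_interval)
classify_fractions(metrics)
#> n = 2000 tracks: 77.0% slow (D <= 0.018 um^2/s), 81.7% constrained
#> (range <= 0.79 um), 75.8% both

fit_mixture_1d(metrics$log10_d, k = 2, seed = 1)
#> Gaussian mixture ( 2 components fitted, 2 effective ) on 2000 values
#>  weight   mean    sd
#>   0.766 -2.489 0.288
#>   0.234 -1.369 0.218
#> log-likelihood: -1239.07 (converged)

palm <- simulate_homer_palm(scene, seed = 1)
cl   <- cluster_palm(palm)
distance_fractions(pop, cl)
#> Distance to nearest PSD center over 2000 trajectories:
#>   within_0.5um: 75.8%
#>   within_1um: 91.8%
```

The fractions read exactly as in a small-quantum-dot experiment: ~3/4 of
receptors are slow and constrained, the log10 D histogram splits into a
dominant slow component near 10^-2.5 µm²/s and a minor fast one near
10^-1.25 µm²/s, and ~75% / ~91% of trajectories lie within 0.5 / 1.0 µm of
a Homer1c cluster center.

A full configuration-driven run (simulation → registration → linking →
metrics → population and synapse analysis → report):

```r
report <- run_pipeline(pipeline_config(preset = "sqd_sa", n_tracks = 1000,
                                       seed = 1))
print(report)
```

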