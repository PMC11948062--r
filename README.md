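# ulmpipe

Super-resolved microvascular imaging from contrast-enhanced ultrasound
(CEUS) clips by **ultrasound localization microscopy (ULM)**, in R.

A low-MI contrast clip shows intravascular microbubbles drowned in tissue
clutter at diffraction-limited resolution (wavelength 0.385 mm at 4 MHz).
ULM recovers vascular structure far below that limit by treating each
bubble as a point emitter: clips are split into 200-frame blocks and clutter
is removed by zeroing the 5 largest components of the spatiotemporal SVD of
each block's Casorati (pixels × frames) matrix; surviving bubbles are
localized to ~0.05 px with the closed-form radial-symmetry center method;
localizations are linked frame to frame by globally optimal assignment
under a 2-wavelength gate (minimum track duration 1 frame); and the
interpolated tracks are accumulated on a 10×-upsampled grid — 10 µm pixels
at the default 0.1 mm pitch — as density, directivity (red toward /
blue away from the probe) and velocity maps. Per-track readouts follow the
field's definitions: velocity (path length over duration, mm/s), dispersity
(fraction of points with a >20° direction change), tortuosity (summed
turning angle over end-to-end distance, deg/mm) and the distance metric
(path over chord, ≥ 1), with region-wise counts and 1st/5th/95th/99th
velocity percentiles relative to a baseline timepoint (T1 = 100%). A
separate layer fits a lognormal bolus to ROI time–intensity curves,

I(t) = b + A/((t−t₀)σ√(2π)) · exp(−(ln(t−t₀)−μ)²/(2σ²)),  t > t₀,

and derives the eleven kinetic parameters (PE, WiAUC, WiPI, WiR, WoAUC,
WiWoAUC, WoR, TTP, RT, mTTl, FT) with explicit, documented conventions.

Because clinical clips cannot ship with the package, a ground-truthed
phantom generator (vessel polylines, moving PSF-convolved bubbles, low-rank
clutter, noise, bolus-shaped arrivals) makes every stage testable; the
`measure_*()` functions wrap the standard validation scenarios. The methods
vignette (`vignettes/ulm-methods.Rmd`) documents the model, conventions and
limitations.

## Worked example

Simulate a two-vessel phantom (4 mm/s down, 2 mm/s up), render a clutter-
dominated clip, and run the chain:

```r
library(ulmpipe)

meta <- acquisition_meta()          # 14 Hz, 4 MHz, 0.1 mm pitch
ph <- vessel_phantom(list(
  list(centerline = rbind(c(4, 1), c(4, 23)), radius = 0.02, speed = 4),
  list(centerline = rbind(c(8, 23), c(8, 1)), radius = 0.02, speed = 2)),
  field_of_view = c(12, 24))
truth <- simulate_bubbles(ph, meta, n_bubbles = 300, duration = 30,
                          max_lifetime_frames = 15, seed = 1)
clip <- render_movie(truth, meta, noise_sigma = 0.03, seed = 2)
clip
#> frame_stack: 420 frames of 121 (axial) x 241 (lateral) px
#>   29.9 s at 14 Hz; pitch 0.1 x 0.1 mm

filt <- svd_filter(clip, filter_params())       # blocks of 200, remove 5
locs <- localize_stack(filt, threshold_k = 20)
tracks <- link_tracks(locs, meta)
tracks
#> track_set: 377 track(s), 4014 localizations
#>   gate 0.770 mm, min duration 1 frame(s)

maps <- accumulate_maps(tracks, meta)           # 10x super-resolved grids
maps
#> ulm_maps: 811 x 2311 fine grid, pitch 0.01 x 0.01 mm (10x upsampled)
#>   total accumulated points: 78435; velocity range 0.00..4.57 mm/s
plot(maps, "directivity")   # red toward probe, blue away

mt <- track_metrics(tracks, meta)
v <- mt$velocity_mm_s[is.finite(mt$velocity_mm_s) & mt$n_points >= 5]
round(velocity_percentiles(v), 2)
#>   p1   p5  p95  p99
#> 1.78 1.97 4.07 4.32
```

The percentiles bracket the two imposed flow speeds: the slow vessel
(2 mm/s) sets the 1st/5th percentiles, the fast one (4 mm/s) the 95th/99th.

Bolus kinetics from a noisy synthetic time–intensity curve:

```r
tic <- simulate_tic(seq(0, 60, by = 1/14), A = 50, mu = 2, sigma = 0.5,
                    t0 = 5, baseline = 1, noise_sigma = 0.3, seed = 3)
fit <- fit_bolus(tic)
fit
#> lognormal bolus fit ('roi'): residual norm 8.661
#>   A = 50.48, mu = 2.008, sigma = 0.5004, t0 = 4.982, baseline = 0.9907
#>   PE 7.113 | TTP 10.8 s | RT 3.82 s | FT 11.2 s | mTTl 5.81 s
```

The fitted parameters sit within ~1% of the generating values; TTP matches
the lognormal mode t₀ + exp(μ − σ²) = 10.75 s, and the rise time is shorter
than the fall time, as the right-skewed bolus model requires.

`run_pipeline(clip, pipeline_config(), "out/")` executes the whole chain and
writes localization/track/metric CSVs, map TIFFs with YAML sidecars, the
whole-field TIC and a run manifest; identical input, configuration and seed
give byte-identical outputs. A thin command-line front end with verbs
`simulate`, `run`, `metrics`, `tic` and `selftest` lives at
`inst/cli/ulmpipe.R`.

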