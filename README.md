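# flyspt

Single-particle tracking PALM (sptPALM) analysis for sparse
photoconvertible-fluorophore movies — the kind of recording used to
track individual mEos2-tagged membrane proteins (e.g. syntaxin1A) in ex
vivo brain tissue at ~10 visible molecules per frame and 30-ms frames.

The package implements the full analysis chain plus a ground-truth
simulator so every stage is verifiable:

* **Detection / localization** — 3×3 median prefilter, scale-normalized
  Laplacian-of-Gaussian filtering
  (`g(x, y, t) = exp(−(x²+y²)/2t) / 2πt`, `t = σ²`), local-maximum
  picking with a per-recording threshold, and subpixel 2D Gaussian
  least-squares refinement that also yields the localization precision
  (fitted SE of the centre, ≈ width/√photons).
* **Tracking** — frame-to-frame linking as a linear assignment problem:
  squared-distance costs, a maximum linking distance beyond which links
  are impossible, and birth/death alternatives at a configurable
  multiple of the maximum cost; solved exactly by a Jonker–Volgenant
  shortest-augmenting-path solver.
* **Mobility** — tracks with 6–1000 spots are analysed; per-track and
  ensemble mean squared displacement
  `MSD(nΔt) = Σᵢ [x(i+n)−x(i)]² + [y(i+n)−y(i)]² / (N−n)`;
  diffusion coefficients from ordinary least squares on the first four
  lags of `MSD(τ) = α + 4Dτ`; mobile/immobile fractions split at
  `log₁₀ D = −1.6`.
* **Paired comparison** — both recordings of a field normalized by the
  baseline MSD value at the 0.30-s peak lag (normalized baseline peak
  ≡ 1), trapezoidal AUC above Y = 0 ignoring sub-10% stray peaks,
  δ mobility = normalized treatment peak − 1, drift QC via the Pearson
  correlation of maximum projections, and Wilcoxon / KS /
  Mann–Whitney / Kruskal–Wallis tests.
* **Simulation** — Brownian mixtures with optional reflecting
  compartments, unconverted → on ↔ dark → bleached photophysics,
  Gaussian PSF rendering (half width 127.9 nm by default), Poisson +
  gain + read-noise camera model, and frame-wise stage drift.

All tabular stages speak tibbles and compose with the pipe; `tidy()` /
`glance()` methods cover the fitted objects and `autoplot()` the curve
types.

## Worked example

Simulate a recording, run the pipeline, and compare a stimulated
(diffusion doubled) recording against its internal baseline:

```r
library(flyspt)

cfg <- sim_config(n_frames = 150, image_size = c(128, 128),
                  n_molecules = 3000, conversion_rate = 0.005, seed = 42)
sim <- simulate_movie(cfg)
sim$movie
#> <spt_movie> 128x128 px, 150 frames, 0.1 um/px, 0.03 s/frame

res <- run_pipeline(sim$movie, pipeline_config(
  detection = detection_config(auto_quantile = 0.999)))
res
#> sptPALM pipeline result
#>   localizations: 6822
#>   tracks: 3253 (159 with 6-1000 spots)
#>   ensemble D: 0.08527 um^2/s, alpha 0.002641 um^2
#>   mobile:immobile = 1.755
```

The ensemble diffusion coefficient (0.085 µm²/s) reflects the simulated
80/20 mixture of mobile (0.1 µm²/s) and immobile (0.001 µm²/s)
molecules; the offset α absorbs the 18-nm localization error
(≈ 4σ² plus the distortion from the immobile fraction). `glance()`
returns the same numbers as a one-row tibble.

```r
pr <- simulate_paired_recording(cfg, stim_factor = 2, render = FALSE)
ens <- function(truth)
  ensemble_msd(track_msds(filter_tracks(truth_tracks(truth)), 0.03, 10), 10)
cmp <- compare_pair(paired_recording(ens(pr$baseline$truth),
                                     ens(pr$treatment$truth)))
cmp
#> sptPALM paired comparison (peak lag 0.3 s)
#>   AUC baseline:  0.1628
#>   AUC treatment: 0.2857
#>   delta mobility: 0.6175
#>   drift Pearson r: NA
```

Doubling D raises the normalized treatment curve above the baseline
peak of 1: δ mobility is +0.62 and the treatment AUC exceeds the
baseline AUC. Across replicates the AUC pairs go into
`paired_test()` (Wilcoxon matched-pairs signed-rank):

```r
paired_test(c(1.02, 0.98, 1.05, 1.01, 0.97, 1.03),
            c(1.31, 1.18, 1.42, 1.25, 1.12, 1.38))
#> # A tibble: 1 × 6
#>   method                             statistic p_value n_pairs n_used defined
#>   <chr>                                  <dbl>   <dbl>   <int>  <int> <lgl>
#> 1 Wilcoxon matched-pairs signed-rank        21  0.0313       6      6 TRUE
```

A command-line wrapper with `simulate`, `detect`, `track`, `msd`,
`compare` and `run` subcommands lives at
`system.file("cli", "flyspt.R", package = "flyspt")`.

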