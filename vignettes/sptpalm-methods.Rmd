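---
title: "Methods: single-particle tracking PALM analysis with flyspt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-particle tracking PALM analysis with flyspt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyspt)
```

# Overview

`flyspt` implements a complete sptPALM (single-particle tracking
photoactivated localization microscopy) analysis chain for sparse
photoconvertible-fluorophore recordings, of the kind used to track
mEos2-tagged membrane proteins such as syntaxin1A in ex vivo brain
tissue. The chain is:

1. **Localize** — per-frame spot detection with a scale-normalized
   Laplacian-of-Gaussian (LoG) filter after a 3x3 median prefilter,
   followed by subpixel 2D Gaussian least-squares refinement.
2. **Track** — frame-to-frame linking by solving a linear assignment
   problem (LAP) over a cost matrix of squared distances with birth and
   death alternatives.
3. **Mobility** — per-track and ensemble mean squared displacement
   (MSD), diffusion coefficients from a four-point linear fit, and the
   mobile-to-immobile ratio.
4. **Compare** — internally controlled paired analysis: baseline-peak
   normalization, area under the normalized MSD curve (AUC), delta
   mobility, drift QC through the Pearson correlation of maximum
   projections, and nonparametric tests.
5. **Simulate** — a ground-truth movie generator with
   photoconversion/blinking/bleaching kinetics, Gaussian PSF rendering
   and EMCCD-style noise, so every stage above is testable against known
   truth.

Every tabular stage takes and returns tibbles, so the pieces compose
with the pipe; movies are plain three-dimensional arrays with pixel
size and frame interval attached.

# Models and algorithms

## Spot detection

Frames are optionally median-filtered (3x3, an exact median-of-9
sorting network) and convolved with the scale-normalized LoG kernel
built from the Gaussian

$$g(x, y, t) = \frac{1}{2\pi t} e^{-\frac{x^2 + y^2}{2t}},$$

with $t = \sigma_{\mathrm{LoG}}^2$. The kernel is negated so bright
blobs of matching scale produce positive maxima and mean-subtracted so
constant offsets map to zero; detection is therefore invariant to
additive background. Candidates are local maxima above a quality
threshold with non-maximum suppression within one $\sigma_{\mathrm{LoG}}$.
The threshold is per-recording: explicit (the reproducible equivalent of
an operator-chosen value) or an upper quantile (default 0.9995,
referenced to 512 x 512 frames at roughly ten spots per frame) of the LoG
response of a reference frame.

Each candidate is refined by least squares against
$b + A\,e^{-((x-x_0)^2+(y-y_0)^2)/2s^2}$ in a 7-px window
(Levenberg–Marquardt with analytic Jacobian). The refinement supplies
the intensity (Gaussian volume), the PSF width, and the localization
precision as the fitted standard error of $x_0$ and $y_0$ — a
Thompson-style estimate that scales as width/$\sqrt{\mathrm{photons}}$.
Fits that do not converge, leave the window, or end at an implausible
width are dropped and counted. Candidates closer than half a window to
the border are discarded.

## Linking

For consecutive frames with $n$ and $m$ detections, an
$(n+m)\times(n+m)$ cost matrix is assembled: squared Euclidean distances
(µm²) in the link block, with pairs beyond the maximum linking distance
forbidden; death/birth alternatives on the diagonals at
`alternative_cost_factor` x (max distance)²; and a zero lower-right
completion block wherever the transposed link is admissible. The matrix
is solved exactly with a Jonker–Volgenant shortest-augmenting-path
solver (deterministic; ties resolved by fixed scan order, so lower
detection indices win). Squared distance is the cost of choice because
it is the negative log-likelihood of a Brownian step.

There is no gap closing and no merge/split handling: a blink ends one
track and starts another, which matches the short modal track lengths
this kind of recording produces. The default maximum linking distance of
0.3 µm (~3 px) is chosen so that a molecule diffusing at 0.1 µm²/s
exceeds it in well under 1% of 30-ms steps
($P(r > 0.3) = e^{-0.3^2/(4 D \Delta t)} \approx 5\times10^{-4}$).

## MSD and diffusion

Tracks with fewer than 6 or more than 1000 spots are excluded. For a
track of $N$ positions the MSD at lag $n\,\Delta t$ averages the
squared displacement over all $N-n$ ordered pairs $(i, i+n)$. Ensemble
curves average per-track curves unweighted at each lag (pair-count
weighting is available); tracks shorter than a lag simply do not
contribute there. The default lag range is 10 lags, 0.03–0.30 s at the
30-ms frame interval, with 0.30 s the conventional "peak" lag.

Diffusion coefficients come from ordinary least squares over the first
four lag points of

$$\mathrm{MSD}(\tau) = \alpha + 4 D \tau,$$

where the intercept $\alpha$ absorbs localization error and finite
exposure; with localization noise of SD $\sigma_{loc}$ per axis,
$\alpha \approx 4\sigma_{loc}^2$ (0.0013 µm² at 18 nm). Tracks whose
four-point fit yields $D \le 0$ (pure noise) are excluded from
log-histograms and the ratio, and counted. The mobile/immobile split is
$\log_{10} D \gtrless -1.6$ (i.e. 0.025 µm²/s); the ratio is flagged
undefined when every track falls on one side.

## Paired comparison and drift QC

The paired design records the same field twice (baseline, then
treatment). Both ensemble curves are divided by a single scalar, the
baseline value at the 0.30-s peak lag, so the normalized baseline peak
is exactly 1; delta mobility is the normalized treatment value at that
lag minus 1. The AUC of each normalized curve is the trapezoidal area
above $Y = 0$; separate above-baseline regions smaller than 10% of the
min-to-max range are ignored, a convention that never triggers on
monotone MSD curves but is implemented as stated. "Peak" means the
0.30-s value by default; for non-monotone curves a maximum-over-lags
option exists.

Paired AUCs are compared with the Wilcoxon matched-pairs signed-rank
test (exact null distribution for small samples without ties; zero
differences dropped, the standard convention; an all-zero comparison is
flagged, not errored). Unpaired group comparisons use Kolmogorov–Smirnov
(two groups; Mann–Whitney as an option) or Kruskal–Wallis (three or
more).

Drift between the two recordings is quantified by the Pearson
correlation of their maximum projections over all pixels, with no
intensity pre-thresholding. No hard $r$ cutoff discards recordings;
instead $r$ and delta mobility are reported together with the
regression of delta on $r$ (slope, R², slope-test p), so drift-driven
attenuation of the response is visible rather than silently removed.

# The simulator

`sim_config()` + `simulate_movie()` generate movies with known truth.
Molecules follow free 2D Brownian motion (per-axis step variance
$2D\Delta t$), optionally confined to reflecting square compartments to
emulate membrane domains — folding the free path with the triangular
reflection map, which is exact for reflected Brownian motion.
Photophysics is a four-state chain, unconverted → on ↔ dark →
bleached, with per-frame probabilities. Rendering samples a symmetric
Gaussian PSF at pixel centres (origin at the top-left pixel centre,
x along columns, 0-based), applies Poisson shot noise on signal plus
background, a gain factor, and Gaussian read noise, and rounds to
16-bit counts. EMCCD excess-noise statistics are deliberately omitted;
they change the noise variance by a constant factor that is absorbed by
the photon-budget calibration and does not affect the downstream
mathematics under test.

Defaults encode the acquisition this pipeline is built around: 512x512
px at 0.1 µm/px (a 16-µm EMCCD pixel behind 100x plus 1.6x
magnification), 30-ms frames, PSF half width (FWHM/2) 127.9 nm (Gaussian
$\sigma \approx 108.6$ nm). Kinetic rates are not measured quantities
anywhere we could take them from, so they are calibrated once to the two
observables such recordings report: bleach 0.10 and blink-off 0.025 per
frame give a mean on-segment of 8 frames; blink-on 0.20 makes the
expected number of on-visits 1.25, so a conversion influx of ~1
molecule/frame (20,000-molecule pool at 5e-5 per frame) sustains ~10
visible molecules per frame. The photon budget (100 photons/frame over
background 6 photons/px, read noise 1) was likewise calibrated once so
the fit-based precision estimate lands near 18 nm. These defaults are
the simulator's definition of "a realistic recording" and are not
adjusted per experiment.

`simulate_paired_recording()` implements the internally controlled
design: both recordings share compartment sites (giving their maximum
projections common structure), and the treatment multiplies D by a
stimulation factor or swaps in a different diffusion mixture. Stage
drift is modelled at two levels, matching how drift corrupts real
recordings: the rendered treatment movie is translated frame by frame
(bilinear interpolation), lowering the max-projection Pearson r; and
the field of view slides off the stimulated region, so the fraction of
molecules carrying the treatment effect falls with the overlap
$(1-|D_x|/W)(1-|D_y|/H)$, which lowers the detectable delta mobility.
The second mechanism is what makes delta correlate *positively* with r
across a drift gradient: translation alone could only inflate apparent
mobility, whereas recordings that physically drift lose the response.

# What the tests do and do not show

The suite verifies, against independent oracles (dense convolution,
exhaustive LAP enumeration, double-loop MSD, closed-form OLS,
exhaustive Wilcoxon sign enumeration), that every algorithmic component
is exact, and, against simulation ground truth, that the integrated
pipeline recovers diffusion coefficients, localization precision, PSF
width, emitter density, detection quality, and the direction of paired
mobility changes. Problem sizes are desk scale — fields of 64–256 px,
40–300 frames, thousands of tracks — chosen so the whole suite runs in
minutes; they are smaller than real recordings (512 px, 16,000 frames,
2000–3000 trajectories per brain), so absolute biological values
(AUC confidence intervals, in-tissue p-values) are out of reach and only
contracts, recoveries and directions are asserted.

The simulator does not emulate: 3D diffusion or defocus, illumination
inhomogeneity (HILO geometry), EMCCD excess noise, autofluorescent
structures, or manual adjustment of photoconversion power during a
recording. Passing tests therefore show the analysis is correct and
well-calibrated for an idealised 2D recording, not that any biological
conclusion transfers.

# Numerical choices

* Coordinates are 0-based pixel centres; µm = px x pixel size. Frames
  are 1-based and consecutive within a track.
* Forbidden assignment entries are a large finite cost (1e9 x the
  alternative cost), keeping the LAP always feasible; the completion
  block contributes zero to the reported total.
* The Gaussian refinement starts from (window centre, LoG scale),
  caps at 100 LM iterations, and rejects fits with width outside
  (0.3 px, 4 sigma_LoG), negative amplitude, centre outside the window,
  or positional SE larger than half the window.
* `ensemble_msd()` uses the sample SD across tracks; a single
  contributing track reports `NA` SD.
* AUC zero-crossings are interpolated linearly before integrating.
* Wilcoxon tests delegate to `stats::wilcox.test` (exact below n = 50
  without ties); the degenerate all-equal case returns a flagged `NA`
  rather than an error so batch comparisons keep running.
* All simulator randomness derives from one integer seed; the analysis
  itself contains no randomness, so pipeline runs are bit-reproducible.

# Known limitations

* No gap closing means blinking fragments long trajectories; diffusion
  estimates are unaffected, but track counts are not comparable across
  blinking regimes.
* The automatic detection threshold quantile is density-dependent and
  referenced to 512x512 frames; small fields or unusual densities
  deserve an explicit threshold (the original workflow set one per
  recording by hand).
* Per-track diffusion coefficients from four lag points are noisy by
  construction; the log10 histogram and the mobile/immobile ratio are
  the intended summaries, not individual track values.
* The Pearson drift metric uses all pixels without Costes-style
  thresholding; variants that threshold first were considered out of
  scope.
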