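---
title: "An efficient-coding pipeline for visual discomfort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An efficient-coding pipeline for visual discomfort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visdiscomfort)
library(dplyr)
```

## The scientific problem

Efficient-coding theories hold that early visual cortex is tuned to the
statistics of natural scenes — in particular to their characteristic Fourier
amplitude spectrum, `A ∝ f^k` with `k ≈ -1` — so that natural inputs evoke
sparse, metabolically cheap population responses. Stimuli that violate these
statistics (high-contrast stripes, band-pass noise with excess mid-frequency
energy, some op-art) are hypothesized to drive large, non-sparse responses and
to be experienced as visually uncomfortable.

This package implements the full analysis chain needed to test that account
on image sets, subjective ratings and steady-state visually evoked potentials
(SSVEPs):

1. **Stimulus synthesis** — calibrated gratings, raised-radial-cosine
   band-pass ("bump") noise, `1/f^k` random-phase noise as a natural-image
   surrogate, and high-contrast stripe textures as an op-art surrogate.
2. **A feed-forward V1 population model** — 500 log-Gabor model cells with
   physiologically motivated tuning distributions; per image the *total
   population output* and the *kurtosis* of the per-cell response vector
   (a sparseness index).
3. **Low-level image statistics** — spectral slope, box-counting fractal
   dimension, RMS contrast, contrast weighted by the Mannos–Sakrison
   contrast sensitivity function (CSF), and first/second-order
   edge-orientation entropy.
4. **SSVEP analysis** — mastoid re-referencing, zero-phase 0.1–40 Hz
   band-pass, 256 Hz resampling, 20 s epochs cut into 2 s sub-epochs with
   ±500 µV artifact rejection, Welch power spectra, and power extraction at
   the 5 Hz fundamental and 10 Hz harmonic over nine posterior channels.
5. **Inference** — PCA over the interrelated statistics with Kaiser
   (eigenvalue > 1) retention, linear mixed models for ratings and SSVEP
   power, and quadratic spatial-frequency tuning fits.

Because the human recordings and the artwork/natural-image sets behind such
studies are not redistributable, the package ships a first-class synthetic
data module: ratings are drawn from a stated linear mixed model and EEG from
a stated signal-plus-1/f-noise model, so that every inferential stage can be
validated by *parameter recovery* against known ground truth.

## Calibration and luminance conventions

Images live in `[0, 1]` with 0.5 as the mid-gray background; physical
luminance is metadata only. All spatial frequencies are in cycles per degree
(c/deg), interpreted through a pixels-per-degree (`ppd`) calibration carried
by every `vd_image`. The default `default_ppd() = 44` derives from the
reference display geometry — a 1024 × 768 raster on a 22-inch CRT (about a
16-inch visible width, ≈2.52 px/mm) viewed from 1 m, where one degree spans
17.46 mm. At that calibration the standard Gaussian-edged aperture (flat
radius 150 px, edge σ 10 px) subtends about 7.3°. Generators refuse
frequencies at or above the Nyquist limit `ppd / 2`.

```{r stimuli}
g <- make_grating(3, ppd = 44, size = 256)
b <- make_bump_noise(3, ppd = 44, size = 256, seed = 1)
n <- make_onef_noise(-1, size = 256, seed = 1, ppd = 44)
g; b
```

### The bump filter

The band-pass noise follows the raised radial cosine construction: in
`v = log2(f / f0)` the gain is 1 for `|v| ≤ (1−β)/(2T)`, rolls off as a
half-cosine, and reaches 0 at `|v| = (1+β)/(2T)`, with `T = 0.9` and
`β = 0.5`. The published rendering of this filter is ambiguous in the source
material we follow; the log-frequency raised cosine used here is the standard
construction for these stimuli and is exposed as `raised_cosine_gain()` so
the choice is inspectable. Note the flat top spans ±0.28 octaves: the peak of
a generated sample's radial spectrum can sit anywhere inside that pass band.

### The temporal envelope

Flickering presentation uses a raised sinusoid `0.5 (1 − cos 2π r t)` at
`r = 5` Hz: contrast grows from zero and fades back to mid-gray each cycle,
so the space-averaged luminance of a mid-gray-balanced stimulus is constant
over time. Whether such protocols ramp contrast monotonically within each
cycle or counter-phase is presentation-specific; the raised sinusoid is the
package's documented choice and gives exactly 100 cycles in a 20 s trial at
60 Hz.

## The V1 population model

`sample_population()` draws cells with:

* peak spatial frequency: log-normal (`meanlog = log 2.2`, `sdlog = 0.65`)
  truncated to 0.5–16 c/deg;
* orientation: a cardinal-biased mixture (35% near 0°, 35% near 90°, with
  15° components, 30% uniform) capturing the oblique effect;
* phase: bimodal at 0°/180° (σ = 25°), approximating reported even/odd
  receptive-field symmetry classes;
* spatial-frequency bandwidth: normal 1.45 ± 0.3 octaves, truncated to
  0.8–2.6;
* orientation bandwidth: uniform 16–17° (half-width at half height).

The physiological literature constrains these distributions only loosely, so
every parameter is overridable through `distribution_params`; the defaults
above are the package's fixed reference conditions. Filters are log-Gabor:
Gaussian in log frequency (half gain at ± half the octave bandwidth),
Gaussian in orientation, exactly zero DC gain, L2-normalized so cells differ
by tuning rather than gain, and one-sided in orientation so the spatial
response is complex and the cell's phase is applied through the quadrature
pair.

`respond()` converts an image to Weber contrast `(pixels − mean)/mean`,
filters, applies the cell phase, half-wave rectifies and averages over
pixels. The **total** output is the sum over cells; an energy (squared
quadrature modulus) alternative sits behind `output = "energy"`. Whether
"total output" in this model family sums rectified responses or energies is
not fixed by the sources; half-wave rectification is the documented default.
**Kurtosis** is the non-excess sample kurtosis `m4/m2²` of the per-cell
vector (switchable to excess). Two consequences worth knowing:

* total response is exactly linear in stimulus contrast (rectification is
  positively homogeneous), and kurtosis is contrast-invariant;
* adding a luminance pedestal rescales Weber contrast by `µ/(µ+a)`: the
  response *pattern* and kurtosis are unchanged while per-cell magnitudes
  scale by that factor — nothing leaks through the zero-DC filters.

```{r v1}
pop <- sample_population(100, seed = 1)
r <- respond(g, pop)
r
respond(vd_image(matrix(0.5, 64, 64), 44), pop)$total   # uniform -> 0
```

## Image statistics

```{r stats}
cfg <- edge_extraction_config(top_edges = 1000)
compute_image_stats(b, id = "bump3", edge_config = cfg) |>
  glimpse()
```

**Spectral slope.** Log amplitude is regressed on log frequency over the
rotationally averaged spectrum (DC and Nyquist excluded). Periodic
one-dimensional patterns have no meaningful slope; they are detected by the
*orientation coherence* of the Hann-windowed power spectrum — the resultant
length of doubled spectral angles, power-weighted. A perfect grating gives 1,
isotropic noise nearly 0; images above 0.5 are flagged `slope_invalid`. This
operationalizes "undefined slope for stripes" robustly: naive
top-coefficient criteria either miss off-bin gratings (leakage) or wrongly
flag steep power-law noise whose lowest annulus legitimately dominates. No
low-frequency cut beyond DC removal is applied to the fit.

**Fractal dimension.** The image is rescaled to 0–255 and posterized at 128
(ties to foreground), zero-padded to the smallest power of two `≥` the
longest side (a 300-px image pads to `2^9 = 512`), and boxes of size
`2^0 … 2^x` are counted. Local slopes `Δ log n / Δ log r` are scanned for the
longest plateau of ≥ 3 slopes agreeing within 0.1; `D` is minus the plateau
mean. Without a plateau a global log–log fit is used and flagged
(`fractal_global_fit`). Slopes where the starting count is already 1 carry no
information and are excluded from plateau search.

**Contrast.** RMS contrast is `sd(pixels)/mean(pixels)` (a full-contrast
sinusoid about mid-gray gives `1/√2`). CSF-filtered ("effective") contrast
weights the contrast spectrum by the Mannos–Sakrison sensitivity
`A(f) = 2.6 (0.0192 + 0.114 f) exp(−(0.114 f)^1.1)`, zero above 60 c/deg and
at DC, and returns the RMS of the filtered contrast image; the implemented
curve peaks near 8 c/deg.

**Edge-orientation entropy.** Images are downscaled to ≤ 340 px, convolved
with 24 odd-symmetric Gabor filters (σ = 1.669 px, orientations 0–π; the
carrier wavelength λ = πσ is the package's documented choice — the sources
fix only σ and the orientation count). Per pixel the strongest absolute
response sets the orientation and intensity, the response sign sets contrast
polarity (extending direction onto 0–360°), 15 px borders are discarded and
the 10,000 strongest responses retained (sub-threshold responses below a
small numerical floor are treated as no edge). First-order entropy is the
Shannon entropy (bits) of the intensity-weighted 24-bin orientation
histogram. Second-order entropy bins every unordered distinct edge pair by
Euclidean distance (500 bins to the image diagonal) and pairwise direction
difference (48 bins over 360°, in stored-edge order), credits the intensity
product to both members' orientation histograms, normalizes per (d, α) cell
(an even spread gives exactly 1/24 per section), and averages the per-cell
entropies over occupied cells. Both entropies are bounded by `log2 24 ≈ 4.58`
bits. The full pair pass is ~5×10⁷ products at 10,000 edges and runs in
compiled code.

## SSVEP analysis

The chain mirrors a standard SSVEP protocol: re-reference to linked mastoids
(M1/M2), zero-phase band-pass 0.1–40 Hz, resample to 256 Hz, epoch 20 s
trials with a 1 s pre-onset baseline subtraction, cut into 2 s sub-epochs,
drop the first (onset transients), reject sub-epochs exceeding ±500 µV on any
analyzed channel, Welch-average per-segment periodograms (2 s segments, zero
overlap, 0.5 Hz resolution), and read power at the exact 5 Hz and 10 Hz bins
averaged over Iz, Oz, O1, O2, POz, PO3, PO4, PO7, PO8.

Numerical choices, all documented and fixed:

* the band-pass is a zero-phase frequency-domain filter with raised-cosine
  transitions (0.05–0.1 Hz and 40–45 Hz) — exactly zero stop-band gain and
  no stability concerns at a 0.1 Hz cut, which forward–backward IIR designs
  struggle with at these normalized frequencies; resampling is likewise
  Fourier-domain (the signal is band-limited well below the target Nyquist);
* the Welch taper defaults to rectangular, which makes an on-bin sinusoid
  leakage-free: a tone of amplitude `a` µV appears as `a²/(2·0.5 Hz) = a²`
  µV²/Hz in the 5 Hz bin and integrates to `a²/2` (Parseval-checked);
  a Hann taper is available;
* "power at 5 Hz" reads the exact bin — the 0.5 Hz grid puts 5 and 10 Hz on
  bins by construction, so no peak search is needed.

Bad-channel detection/interpolation and ocular-artifact regression are out of
scope here: synthetic recordings contain no such artifacts unless injected,
and injected transients are handled by the amplitude rejection.

```{r ssvep}
truth <- synthetic_ground_truth(ssvep_amplitude_map = c(bump3 = 2),
                                noise_sd_uv = 1, seed = 2)
rec <- generate_synthetic_eeg("bump3", truth, n_channels = 13, fs_hz = 256)
analyze_ssvep(rec)
```

## Inference

`pca_image_stats()` performs correlation-matrix PCA (variables are z-scored
— the statistics have incommensurate units, so covariance PCA would be
dominated by scale) over slope, fractal dimension, RMS and CSF contrast,
total model response and both entropies, excluding slope-invalid (periodic)
rows. Components with eigenvalue > 1 are retained (Kaiser); `retain =`
overrides the rule explicitly and the override is recorded, supporting the
common practice of carrying a near-threshold third component. Loadings are
signed so each component's dominant variable is positive.

`fit_rating_model()` and `fit_sf_tuning()` wrap lmerTest: the scientific
contract is the model structure (fixed effects plus an observer random
intercept, optional random slope), not a bespoke optimizer. Coefficients are
reported with Wald 95% intervals and Satterthwaite p values; marginal and
conditional R² follow the fixed/total variance decomposition. Likert ratings
are treated as numeric, matching the primary analysis convention for such
designs; an ordinal re-analysis is a deliberate non-goal. No multiple-testing
correction is applied, and the report footer says so. Spatial-frequency
tuning is fit on the octave scale `log2 f` (standard for SF tuning) with
linear + quadratic terms, image type and a linear-by-type interaction;
`vertex_frequency()` returns the quadratic's peak/trough back in c/deg.

### The synthetic ratings generator

Ratings follow `intercept + Xβ + b_observer + ε` with z-scored predictors,
`b ~ N(0, observer_sd²)`, `ε ~ N(0, residual_sd²)`, rounded and clipped onto
the 1–7 Likert scale. Defaults (11 observers, intercept 4, observer SD 0.3,
residual SD 0.8) keep essentially all mass inside the scale so
rounding-plus-clipping stays a small perturbation. `likert = FALSE` exposes
the continuous latent rating: with zero noise the mixed model then recovers
the generating coefficients to machine precision, a contract that integer
rounding would destroy. What passing recovery tests shows is that the
*inference machinery* is calibrated for data that truly follow the generative
model; real ratings add ordinality, observer-specific scale use and semantic
effects that this generator deliberately does not emulate.

## The end-to-end synthetic study

`run_full_synthetic_study()` chains everything: build a 48-image battery
(18 `1/f^k` natural surrogates with k spread over −1.3…−0.7, 10 bumps, 10
gratings, 10 stripe textures; 128-px images at 24 ppd), compute model
responses (500 cells, peaks capped with headroom below the 12 c/deg Nyquist)
and image statistics (3000 retained edges per image), simulate ratings for
11 observers and EEG (3 trials per condition at 256 Hz, 5 Hz amplitudes tied
to each image's effective contrast), run the SSVEP chain, the PCA and all
fits, and emit the report as CSVs plus a plain-text summary. These problem
sizes are the package's stated desk-scale reference conditions; every stage
is the same code that runs at larger sizes. The run is deterministic: one
master seed derives all stage seeds, and repeated runs emit byte-identical
CSVs.

```{r study, eval = FALSE}
res <- run_full_synthetic_study(study_config(seed = 1), out_dir = "report")
glance(res$pca)
tidy(res$fit_model_outputs)
```

## Known limitations

* The synthetic battery contains no real artworks or photographs; surrogate
  categories reproduce the target statistics (spectral slope, contrast,
  periodicity), not semantic or compositional structure.
* The periodicity (slope-validity) statistic is tuned to distinguish
  one-dimensional periodic patterns from isotropic fields; strongly oriented
  natural textures could in principle cross the 0.5 threshold and should be
  inspected via the reported `coherence` value.
* The V1 model is purely feed-forward: no divisive normalization, cortical
  magnification or chromatic channels.
* EEG preprocessing assumes the synthetic container; EDF import and
  bad-channel interpolation are not implemented.
* Population tuning distributions are parametric approximations constrained
  only loosely by the cited physiology; conclusions that hinge on their
  exact shape should vary `distribution_params`.
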