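---
title: "Quantitative image properties: models, conventions and limitations"
author: "qipr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative image properties: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qipr)
```

# Scope

`qipr` computes the global image statistics ("quantitative image
properties", QIPs) that empirical aesthetics and vision science use to
characterize pictures: dimensions, contrast and entropy statistics,
perceptual balance and symmetry, oriented-gradient and Gabor-edge measures,
Fourier-spectrum scale-invariance statistics, box-counting fractal
dimensions, and variance statistics of first-layer convolutional filter
responses. A batch runner exports one CSV row per image over a fixed
46-column schema (`list_measures()`).

Because these measures are sensitive to implementation minutiae —
resampling, color conversion, binning, frequency exclusion — this vignette
records every such choice, the synthetic ground truth the package validates
itself against, and the limitations of that validation.

# Input normalization

All measures consume 8-bit sRGB raster images (`load_image()`: PNG, JPEG,
TIFF). Grayscale files are promoted to three equal channels, alpha is
composited over white, 16-bit depth is rescaled. Conversions:

* **Gray (8-bit)** uses the legacy luma weights 0.299/0.587/0.114. The
  weights are a documented constant so that parity checks against other
  implementations are possible.
* **CIELAB** assumes sRGB primaries and D65 white, with one shared
  conversion for every measure (including the L*-channel spectral
  protocol, which historically used a proprietary tool's conversion).
  Internal consistency across the suite was preferred over per-measure
  historical fidelity; conversions agree with `grDevices::convertColor`
  to fractions of a unit per channel.
* **HSV** channels are all on [0, 1). Hue statistics are plain linear
  mean/SD, not circular statistics — matching the scripts this suite is
  modeled on; a circular alternative is out of scope.

Resampling is bilinear with pixel-center alignment everywhere
(`standardize_size()`), with six policies: longest side, total pixel
count, fixed square, maximum pixel cap (never upscales; aspect preserved
within 2%), centered power-of-two square crop, and mean-gray square
padding.

# Histogram statistics

Entropies use 256 equal-width bins over the channel's full declared range
(L* over 0–100, hue over [0, 1)). The count is not dictated by the
original description; 256 matches 8-bit provenance and makes the uniform
maximum exactly 8 bits. Standard deviations are population SDs throughout
so values are bit-comparable across implementations.

# Balance and symmetry

Pixel coordinates are 0-based pixel centers; the geometric center is
((W−1)/2, (H−1)/2).

* **Balance (APB)** averages the percent mass imbalance
  100·|M₁−M₂|/(M₁+M₂) over eight pairs of equally sized areas: the two
  half-planes across each of the four main axes (vertical, horizontal,
  two corner-to-corner diagonals), plus, per axis, the two outer strips
  beyond a pair of lines parallel to the axis. The parallel lines are
  placed symmetrically about the axis so that the band between them holds
  half the image (the 25%/75% positions whenever the extent divides
  evenly; on diagonals the threshold acts on the absolute signed offset,
  with the cut chosen so the enclosed area is closest to one half). Two
  design points deserve emphasis: the pair is the two *outer* strips, not
  inner-versus-outer, and the threshold is symmetric in the offset. Both
  follow from the requirement — used as an exact test invariant — that an
  image symmetric under all four axis reflections scores exactly 0; a
  one-sided quantile band or an inner-vs-outer comparison both violate it.
  Pixels exactly on an axis belong to neither half; a pair with no mass
  contributes 0 (balanced).
* **DCM** is the distance from the center of perceptual mass to the
  geometric center, as a percentage of the center-to-corner-pixel-center
  distance. Mass is 255−gray (dark-heavy, default) or gray (bright-heavy).
* **Mirror symmetry** per axis is 100·(1 − mean|I − mirror(I)|/255);
  square images average four axes, non-square ones the vertical and
  horizontal axes only. Even-sized axes pair pixel i with N−1−i; only the
  central line of an odd size is self-paired.
* **Homogeneity** binarizes with Otsu's threshold on the 256-bin gray
  histogram (black = strictly below), counts black pixels in a 10×10 grid
  with boundaries at round(k·side/10), and reports normalized entropies:
  over cells (/log₂ 100 ≈ 6.64 bits), over row sums (/log₂ 10) and column
  sums; the headline value is the mean of the row and column components.

Degenerate inputs (no mass under the chosen polarity; constant images for
Otsu) return NaN with a warning rather than an arbitrary number.

# Oriented gradients (HOG family)

The combined gradient image takes, per pixel, the strongest
central-difference gradient magnitude among the L*, a*, b* channels
(replicate borders), with the winning channel's orientation; ties resolve
in L*, a*, b* order. The stated description ("highest value among the
three") is ambiguous between max-of-magnitudes and magnitude-of-max; this
package uses max-of-magnitudes, which keeps the step-edge response in
closed form.

Orientation histograms use 16 equal bins over the full signed 360°, bin 1
centered at 0°. The pyramid has levels 0–3 with 1/4/16/64 sections
(boundaries at round(k·side/2^l)); level-by-level gradient mass is
conserved to within 1e−6 relative error, which is tested. Levels above 3
are refused — small sections make the histograms unstable.

* **Complexity** is the mean gradient strength (size-dependent; the batch
  default resizes to 100,000 total pixels first).
* **Self-similarity (PHOG)** normalizes every section histogram and the
  ground histogram to sum 1 and averages histogram-intersection-kernel
  scores over the sections of levels 1–3 (equal weights by default).
  Sections with zero gradient mass contribute 0.
* **Anisotropy** is the population SD of the 16 bin values of the
  bin-wise-summed, sum-normalized level-3 histograms; 0 for uniform
  orientation content, √15/16 for a one-hot distribution.

# Gabor edges and orientation entropy

The bank holds 24 quadrature pairs at 15° spacing (wavelength 8 px,
envelope σ = 4 px, unit aspect), even kernels DC-corrected inside the
envelope. Only the count (24) and the 360° coverage are dictated by the
measures' provenance; the scale parameters were chosen so the bank is
DC-free and orientation-selective at the capped working resolution, and
are exposed as arguments. Images are capped at 120,000 pixels before
filtering; filtering is circular (FFT), so toroidal translations are exact
symmetries.

* **Edge density** sums quadrature energy over all pixels and all 24
  filters.
* **First-order EOE** is the entropy of the strength-weighted dominant-
  orientation histogram.
* **Second-order EOE** takes the 10,000 strongest edge pixels (no
  non-maximum suppression; ties broken by pixel index), enumerates every
  unordered pair at Euclidean distance ≥ 20 px exactly (batched, never
  sampled), and returns the entropy of the 24-bin histogram of pairwise
  orientation differences mod 360°.

A note on an invariance: rotating a *drawn* line pattern by one bank step
(15°) changes EOE values by 0.1–0.8 bits because rasterization leaks
orientation energy into neighboring bins differently at different angles.
The exact content of the rotation property is label permutation, and that
is what the tests assert (permuting the labels of a computed edge field
leaves both entropies unchanged to machine precision).

# Fourier spectrum protocols

`radial_spectrum()` averages DFT amplitude (or power) over annuli of
rounded integer radius 1…N/2 cycles/image; DC is excluded. Three published
slope protocols are implemented (`fourier_slope()`):

| | spehar | redies | mather |
|---|---|---|---|
| channel | 8-bit gray | 8-bit gray | CIELAB L* |
| size | crop to power-of-two square | pad square (mean gray), resize 1024² | crop pow2 square, resize 1024² |
| spectrum | amplitude | power | amplitude |
| exclusion | Cook's distance pruning | keep 10–256 cycles/image | drop lowest/highest quartile of radii |
| binning | none | 100 equal log₁₀-frequency bins | none |

Numerical choices: the influence cutoff for the spehar protocol is the
conventional 4/m (m = fitted points; one pruning pass, one refit), exposed
as a parameter — the printed description of the original ("n/4" with n the
half-width) conflicts with standard practice and would essentially never
prune. Log-binning uses bin-mean log power at bin-mean log frequency,
empty bins dropped. **Sigma** is the mean squared residual about the
redies-protocol line, evaluated at all raw points (default; known to
over-represent high frequencies) or at the binned points.

A caveat the tests respect: resizing *up* to 1024² (redies/mather on
smaller inputs) multiplies the spectrum by the interpolation filter
response, which shifts slopes by an image-independent amount — rank
correlations across images are unaffected (this is why the concordance
checks may use 512² inputs), but absolute slope recovery is only unbiased
at the protocols' native 1024². Parameter-recovery tests therefore run at
1024².

# Box-counting fractal dimensions

* **2D**: center-crop to the largest power-of-two square, binarize at mean
  lightness, mark boundary pixels (value differs from right or lower
  neighbor), and count boxes containing boundary pixels for box sides
  side/2 … 4; D is the OLS slope of log₂N vs log₂(1/L) over occupied
  scales. An axis-aligned half-plane gives N(L) = side/L exactly and
  D = 1.
* **3D (differential)**: on the L* surface (rescaled to 0–255) over the
  largest centered power-of-two square (the power-of-two constraint keeps
  the box schedule integral; the source description says only "largest
  central square"), each s×s column contributes floor(range/h)+1 boxes
  with h = s·255/side, s = side/2 … 4; D is the OLS slope of ln N vs
  ln(1/s). A planar ramp gives exactly D = 2. Out-of-range fits are
  reported as-is, never clamped.

**Known limitation.** Differential box counting underestimates high
dimensions on Gaussian rough surfaces: the expected range over a small box
grows faster than s^H (an extreme-value effect over the points in the
box), which flattens the fine-scale log-log curve. At 512²–1024², fBm
surfaces with H = 0.5 and 0.8 recover D = 3−H within ±0.15, but H = 0.2
(D = 2.8) recovers only ≈ 2.59, and the corresponding test expectation is
left failing deliberately rather than widening the tolerance. Rank
ordering across surfaces is unaffected, which is what the 2D/3D
concordance result relies on.

# CNN-feature measures

The filter bank is 96 kernels of 11×11×3 applied at stride 4. The working
input is a single bilinear resize to 511×511 — the nominal 512 minus a
one-pixel trim applied *as part of the resize* rather than as a crop. The
odd side makes the 126×126 response lattice closed under reflection, so a
mirrored composite scores symmetry exactly 1; folding the trim into the
resize (rather than resize-512-then-crop) additionally makes
sym(img) = sym(flip(img)) exact, which the crop variant violates by ~1e−3.

Symmetry compares the rectified response stack against the stack computed
with axis-flipped kernels and mapped back onto the lattice:
Σmin/Σmax over all filters and positions; the combined left-right-up-down
variant intersects four stacks and can only be ≤ either single-axis score.
Self-similarity compares per-filter max-response histograms of an 8×8
partition against the whole-image histogram (histogram intersection
kernel, median over sections). Sparseness is the mean over the 8×8
subregions of the variance across the 96 pooled filter responses;
variability is the median over filters of the variance of each filter's
pooled responses across subregions (population variances; the partition
size n = 8 mirrors the self-similarity grid and is configurable — the
original's value is not stated).

By default the bank is a seeded surrogate: 64 oriented Gabor luminance
kernels (16 orientations × 2 wavelengths × 2 phases) and 32 color-opponent
center-surround kernels (red-green and blue-yellow, two polarities, four
widths), all zero-mean, unit L2 norm, deterministic given the seed.
Pretrained first-layer weights can be supplied as a raw float32
96×3×11×11 tensor (`load_filter_bank()`, optional MD5 check); they are
never downloaded. With the zero-mean surrogate and per-image mean
subtraction, a constant image produces an all-zero stack, so the CNN
measures return NaN with a warning (a bank with DC response would instead
give self-similarity 1; the degenerate-input contract takes precedence).

# Synthetic ground truth

Every measure is validated against generators whose truth is known by
construction (`random_phase_image`, `fbm_surface`, `line_pattern`,
`mirrored_composite`, `tiled_texture`, plus step/grating/constant
fixtures). Generators are pure functions of (parameters, seed), use an
isolated RNG scope keyed by a per-generator tag (adding generators never
shifts existing fixtures), and restore the session RNG state.

Two generator choices matter:

* **Quantization.** Synthesis rescales to the [0, 255] range but keeps
  continuous values by default (`quantize = TRUE` rounds). Rounding
  imposes a flat quantization noise floor that dominates the high
  frequencies of steep-spectrum images and would defeat the generator's
  own slope ground truth; continuous output keeps the constructed
  spectrum exact while remaining on the 8-bit scale.
* **fBm aliasing.** A sampled continuous fBm process has the alias-folded
  spectrum, not the bare power law; `fbm_surface` therefore sums the
  spectral replicas (six shifts per axis). Without this the fine-scale
  increments are markedly too smooth (effective local H ≈ 0.5) and the
  surface's box-counting dimension is wrong for reasons unrelated to the
  estimator.

What passing these tests does *not* show: natural images and artworks
violate the generators' stationarity, Gaussianity and phase randomness;
absolute agreement with other implementations on real photographs still
depends on resampling and color-conversion parity, which is why those
conventions are pinned down above.

# Problem sizes used in the test-suite

The routine test suite scales simulations for a short run: the slope/
fractal concordance panel uses 60 random-phase images at 512² (the
acceptance script reruns the full 200), parameter recovery uses 3
replicates per exponent at 1024², and fBm recovery uses 3 surfaces per
Hurst value at 512². Thresholds are never adjusted to the scaled sizes.

# Batch interface

`run_batch()` processes files/directories in sorted order, isolates
per-image failures (NA row plus reason in an `error` column), and writes
locale-independent CSV (UTF-8, '.' decimal, LF, NA as empty cell). The
full roster enumerates 46 value columns; descriptions that count "43
properties" group the slope variants and symmetry axes differently. A
thin command-line wrapper ships in `inst/cli/qip-batch.R`
(`--input, --measures, --config, --out, --seed, --cnn-weights,
--log-level, --list`). Execution is single-threaded by design; users
parallelize by sharding input lists.
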