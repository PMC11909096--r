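# qipr — quantitative image properties for empirical aesthetics

Researchers in empirical aesthetics and vision science summarize pictures
with *quantitative image properties* (QIPs): objective scalars computed
from pixel data, independent of any observer — contrast, entropy, balance,
symmetry, fractality, spectral scale-invariance, self-similarity. Results
across labs are notoriously hard to compare because each group's scripts
differ in resampling, color conversion and fitting details. `qipr`
implements the full roster of these measures in R as one coherent, tested
library with pinned-down conventions, a deterministic synthetic-image
generator that provides ground truth for every measure, and a batch runner
that writes one CSV row of measures per image.

## The measures

For an 8-bit RGB image the package computes 46 values (`list_measures()`),
grouped as:

* **Dimensions** — image size (default W + H) and aspect ratio W/H.
* **Contrast & entropy** — RMS contrast (population SD of CIELAB L*),
  Shannon entropy of the L* histogram and of the HSV hue histogram
  (256 bins), and mean/SD of all nine R, G, B, L*, a*, b*, H, S, V
  channels.
* **Balance & symmetry** — the APB Balance score (mean percent mass
  imbalance over eight axis-defined pairs of equally sized areas,
  `100·|M₁−M₂|/(M₁+M₂)`), deviation of the center of mass (DCM, percent of
  the maximal center-to-corner distance), mirror symmetry about the main
  axes, homogeneity of the Otsu-binarized black-pixel distribution over a
  10×10 grid, and CNN-feature symmetry (left-right, up-down, combined)
  from first-layer filter responses.
* **Scale invariance** — the Fourier spectrum slope α from the log-log
  regression of the radially averaged spectrum under three published
  protocols (amplitude spectrum with Cook's-distance pruning; power
  spectrum over 10–256 cycles/image with log-binning; L*-channel amplitude
  spectrum over the middle frequency quartiles), the Fourier sigma
  (mean squared residual about that line), and 2D (binarized boundary,
  D ∈ [1,2]) and 3D (differential, D ∈ [2,3]) box-counting fractal
  dimensions.
* **Self-similarity & feature statistics** — PHOG self-similarity
  (histogram-intersection of oriented-gradient histograms across pyramid
  levels 0–3), CNN self-similarity, HOG complexity and anisotropy, Gabor
  edge density, first- and second-order edge-orientation entropy (24
  orientations; pairwise orientation differences of the 10,000 strongest
  edges at ≥ 20 px distance), and CNN sparseness/variability (variances of
  max-pooled first-layer responses).

The methods vignette (`vignettes/qip-methods.Rmd`) documents every
numerical convention, the design decisions behind them, and known
limitations.

## Worked example

Measure a synthetic random-phase image with a prescribed amplitude-spectrum
exponent of 1.2 — a stimulus whose ground truth is known by construction:

```r
library(qipr)
img <- random_phase_image(512, alpha = 1.2, seed = 42)
rgb <- qip_image(array(rep(img$pixels, 3), c(512, 512, 3)), source_id = "demo")
vals <- compute_measures(rgb, c(
  "img_size_sum", "rms_contrast", "lightness_entropy", "balance", "dcm",
  "mirror_symmetry", "homogeneity", "fourier_slope_spehar",
  "fourier_slope_redies", "fourier_slope_mather", "fractal_dim_2d",
  "fractal_dim_3d", "self_sim_phog", "anisotropy"))
round(vals, 4)
#>         img_size_sum         rms_contrast    lightness_entropy
#>            1024.0000              10.6246               6.8034
#>              balance                  dcm      mirror_symmetry
#>               3.9771               2.1411              88.2575
#>          homogeneity fourier_slope_spehar fourier_slope_redies
#>              97.4576              -1.1985              -2.8372
#> fourier_slope_mather       fractal_dim_2d       fractal_dim_3d
#>              -2.7022               1.8551               2.4859
#>        self_sim_phog           anisotropy
#>               0.9573               0.0008
```

Reading the numbers: the Spehar-protocol slope recovers the constructed
exponent (−1.20 for α = 1.2; the other two protocols operate at 1024² and
carry a constant resampling offset on 512² inputs, which leaves rank
comparisons across images untouched). The isotropic noise texture is
nearly balanced (Balance ≈ 4, DCM ≈ 2), spatially homogeneous (≈ 97), has
no preferred orientation (anisotropy ≈ 0.001) and is highly self-similar
(PHOG ≈ 0.96). A shallower exponent would raise both fractal dimensions;
a steeper one lowers them.

Batch over a folder, from the shell:

```sh
Rscript inst/cli/qip-batch.R --input photos/ --measures all --out results.csv
Rscript inst/cli/qip-batch.R --list        # measure schema
```

## License

MIT.
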