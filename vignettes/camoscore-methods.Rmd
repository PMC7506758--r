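---
title: "Scoring camouflage effectiveness: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring camouflage effectiveness: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camoscore)
```

## The problem

Camouflage works by matching the colors and spatial structure of a
background as they appear to an observer — not as they appear pixel by
pixel to a sensor. camoscore scores a set of M candidate camouflage
patterns against N background images with two complementary metrics and
fuses them into a single conspicuousness score per pattern. Lower scores
mean a harder-to-detect pattern. Scores are relative within one run: they
rank the supplied patterns against the supplied backgrounds and carry no
absolute meaning across stimulus sets.

## Color difference in spatial CIELAB (ICSI)

Plain CIELAB treats every pixel independently, so a fine-grained texture of
clashing colors that the eye blurs into a neutral tone would be scored as a
gross mismatch. The spatial CIELAB pipeline fixes this by filtering images
the way the human visual system does before measuring color differences:

1. Device RGB is linearized and mapped to CIE XYZ. We assume an sRGB
   display (`srgb_characterization()`); a measured characterization can be
   plugged in, and should be when the display is known not to be sRGB.
2. XYZ is decomposed into one achromatic and two chromatic opponent
   channels with the standard 3×3 opponent matrix.
3. Each opponent channel is convolved with its contrast-sensitivity
   low-pass kernel, a sum of Gaussians specified in degrees of visual
   angle. The chromatic kernels are much broader than the achromatic one,
   reflecting the eye's poor spatial resolution for color.
4. The filtered result returns to XYZ and then to CIELAB (D65 white,
   Y-normalized, consistent with the sRGB assumption).

The per-pixel color difference map is the Euclidean Lab distance
`ICS(u,v) = sqrt(dL*² + da*² + db*²)`, and the color metric is its
**population standard deviation** (divide by the pixel count):

`ICSI = sd(ICS)`

Pooling by standard deviation rather than the mean makes ICSI a measure of
how *unevenly* a pattern differs from the background. A consequence worth
stating loudly: **a spatially uniform color offset — even a large one —
contributes nothing to ICSI.** Two mismatched uniform color fields score as
a perfect match, and a pattern whose colors straddle the background's color
(difference map near zero in places, large in others) can score worse than
a pattern that is uniformly somewhat off. This is the metric as defined;
when mean color error matters for your application, enable
`pair_config(include_mean = TRUE)` to report the mean ICS alongside.

### Viewing geometry

The kernels live in degrees of visual angle; images live in pixels. The
bridge is samples per degree, `spd = (π/180)·distance/pitch` (small-angle
approximation; error below 0.01% at one degree). The display's physical
pixel pitch is a required input because image resolution alone cannot
determine it; the package default of 35 spd corresponds to an observer at
55 cm from a typical 24-inch full-HD panel. Larger spd means the observer
resolves less spatial detail per pixel, so the pixel-domain kernels widen
proportionally.

### Filter parameters and numerical choices

The opponent matrix and the per-channel Gaussian weights and spreads are
read from one editable YAML file
(`system.file("extdata", "scielab-filters.yaml", package = "camoscore")`);
the packaged values are the published reference constants of the spatial
CIELAB filters. Numerical choices, made once and applied everywhere:

- The "halfwidth" parameters are interpreted as the Gaussian sigma in
  degrees; realized sigma in pixels is `halfwidth_deg * spd`, truncated at
  ±3 sigma with a minimum 3×3 support (a sub-pixel sigma thus degrades
  gracefully to a near-delta kernel; no special fallback is needed).
- The achromatic filter's negative surround lobe is kept as specified;
  only the summed kernel is renormalized to unit sum, so uniform fields
  pass through bit-for-bit (verified to 1e-6 in the tests, observed at
  ~1e-13).
- Convolution uses symmetric (mirror) boundary padding, applied separably
  per Gaussian term; by linearity this equals 2-D convolution with the
  summed kernel. Padding is folded into a dense banded operator, which
  keeps constants exact and handles kernels wider than the image.
- Opponent-channel filtering can push XYZ slightly negative; values are
  clipped at 0 before the CIELAB nonlinearity.

## Texture difference from gradient magnitudes (GMSD)

Texture is compared on Sobel gradient magnitude fields
`S = sqrt((s_h ⊗ I)² + (s_v ⊗ I)²)` computed on a single luminance plane —
by default CIE Y from the same display characterization, keeping the
texture path consistent with the color path (`channel_policy = "gray"`
selects Rec.601 luma on encoded values instead). The per-pixel similarity

`GMS(u,v) = (2·Si·Sj + c) / (Si² + Sj² + c)`

lies in (0, 1], with the stability constant `c` (default 0.0026 for
[0,1]-ranged luminance, configurable) keeping flat-versus-flat regions at a
perfect score instead of 0/0. The texture metric is again the population
standard deviation, `GMSD = sd(GMS)`, which is 0 for structurally identical
pairs and bounded by 0.5. Both metrics are symmetric in their arguments
and exactly zero for identical images.

## Entropy weighting and the final score

Every camouflage/background pair yields a value `x[i,j,k]` for each metric
k. Each metric slice is normalized to proportions
`p[i,j] = x[i,j] / Σ x`, its normalized Shannon entropy is
`e = -Σ p·ln p / ln(MN)` (with `0·ln 0 = 0`), and the weights are
`w_k = (1 - e_k) / Σ(1 - e)`. A metric that barely discriminates between
pairs has entropy near 1 and weight near 0; a metric that is exactly
constant across pairs (or all zero) is uninformative and receives weight 0.
If every metric is uninformative the package falls back to equal weights
with a warning rather than aborting a batch run. Because the proportions
are scale-free, weights are invariant to rescaling a metric — but note the
raw (unnormalized) `x` values are what the weights are applied to, so the
metric with the larger numeric range (typically ICSI, in Lab units)
dominates the score's absolute magnitude.

The score of pattern i is the weighted mean of its differences over all
backgrounds:

`v_i = Σ_k w_k · mean_j x[i,j,k]`

This per-camouflage orientation is the default, since the question asked is
"which pattern is least conspicuous across these scenes"; the transposed
per-background aggregation (scoring each scene by the mean over patterns)
is available via `orientation = "per_background"`. Ranks are ascending in
score — rank 1 is the most effective camouflage — with ties kept in input
order.

Agreement with human detection data (hit rate, detection time, rated
difficulty per pattern) is evaluated as the absolute Pearson correlation,
so indicators of opposite polarity compare on one 0–1 scale
(`correlate_with_subjective()`).

## The synthetic stimulus generator

All tests and the acceptance study run on seeded synthetic stimuli: a
uniform base color plus Gaussian white noise blurred by a Gaussian of
`smoothing_sigma_px` and standardized to unit variance, so
`noise_amplitude` is the per-channel texture contrast in [0,1] units and
`smoothing_sigma_px` its spatial scale. The same seed reproduces images
bit-for-bit; the background of a pair uses sub-seed `seed + 1000003`.
`canonical_fixture_set()` emulates the reference psychophysics layout — six
camouflage palettes (woodland, multicam, marpat, desert, navy, urban) as
100×300-pixel patches against three sea-state backgrounds sharing an ocean
base color — at a 480×270 background size, which keeps the 16:9 display
aspect at a size the full study completes in seconds.

What the generator does *not* emulate: natural images' oriented,
multi-scale, non-Gaussian structure, specular glints, illumination
gradients, or real camouflage macro-patterns. Passing the packaged studies
therefore demonstrates the pipeline's internal correctness and its ability
to rank graded background fidelity, not field performance on photographs.

`ranking_recovery_study()` is the end-to-end check: camouflage variants are
created by perturbing a background with noise at amplitudes
{0, 0.05, 0.1, 0.2} and must be ranked in amplitude order by the final
score; across 40 seeded repetitions at 48×48 pixels the recovery rate is
the reported statistic (1.0 in the packaged runs).

## Degenerate inputs and edge cases

- Images below 3×3, channel counts other than 3 (after grayscale
  replication / alpha dropping), and non-finite pixels are rejected at
  construction.
- Resolution equalization: `resize` (bicubic, Keys a = −0.5, edge-clamped)
  resamples the background to the camouflage patch's dimensions; `crop`
  takes the centered common region, which is the closest analogue of
  comparing a patch with the background region it overlaps. Equal-size
  pairs pass through untouched under either policy.
- `entropy_weights` on a single cell (M = N = 1) is undefined
  (`ln(MN) = 0`) and falls back to equal weights with a warning.
- An all-zero difference matrix (every pattern identical to every
  background) yields all-zero scores with ties in input order.

## Problem sizes

The packaged test suite and acceptance study use: 16×16 pairs for oracle
equivalence (25 pairs), 24×24 identity pairs (20), 48×48 ranking-recovery
images (40 repetitions × 4 variants × 3 backgrounds), and the canonical
6×3 run at 100×300 patches against 480×270 backgrounds. These sizes are
the package's chosen study conditions; the implementation itself handles
arbitrary sizes, with the dense convolution operators sized by the image
dimensions.
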