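# camoscore

Scores how conspicuous camouflage patterns are against sets of background
images, for researchers quantifying background matching — in visual
ecology, pattern design, or psychophysics — who need an objective stand-in
for human detection experiments.

## The method

For M camouflage patches and N backgrounds, every pair `(i, j)` is compared
with two metrics after resolution equalization:

- **ICSI** (color): both images are transformed to S-CIELAB — device RGB →
  XYZ → opponent channels → low-pass filtering matched to the observer's
  viewing distance (samples per degree) → CIELAB — and the per-pixel
  Euclidean distance map `ICS(u,v) = √(ΔL*² + Δa*² + Δb*²)` is pooled as
  its population standard deviation.
- **GMSD** (texture): Sobel gradient magnitudes `S_i`, `S_j` of the
  luminance plane are compared per pixel by
  `GMS(u,v) = (2·S_i·S_j + c)/(S_i² + S_j² + c)`, pooled again as the
  population standard deviation.

The M×N×2 difference matrix is fused by the entropy weight method: each
metric's values are normalized to proportions `p_ijk = x_ijk / Σx_..k`,
their normalized entropy `e_k = −Σ p ln p / ln(MN)` is computed, and
`ω_k = (1−e_k)/Σ(1−e)` weights the metric — a metric that discriminates
more between pairs gets more weight. The conspicuousness score of pattern
i is `v_i = Σ_k ω_k · mean_j x_ijk`; **lower score = more effective
camouflage**. Agreement with subjective detection data is reported as the
absolute Pearson correlation |r|.

## Worked example

```r
library(camoscore)

fx <- canonical_fixture_set(seed = 7)          # 6 synthetic patterns, 3 sea backgrounds
x  <- build_difference_matrix(fx$camos, fx$backgrounds, viewing_geometry(spd = 35))
w  <- entropy_weights(x)
aggregate_scores(x, w)
```

```
Camouflage conspicuousness scores (lower score = more effective camouflage)
orientation: per_camouflage; weights: icsi=0.9565 gmsd=0.0435
 pattern_id icsi_mean gmsd_mean weight_icsi weight_gmsd score rank
     desert     14.49    0.2632      0.9565     0.04354 13.87    1
      urban     14.96    0.2479      0.9565     0.04354 14.32    2
   multicam     15.46    0.2663      0.9565     0.04354 14.80    3
   woodland     18.57    0.2751      0.9565     0.04354 17.77    4
     marpat     18.71    0.2645      0.9565     0.04354 17.90    5
       navy     19.84    0.2658      0.9565     0.04354 18.98    6
```

ICSI varies far more across these pairs than GMSD, so it receives ~96% of
the weight; `desert` (smooth, low-contrast texture) produces the most
uniform difference maps against the sea backgrounds and ranks best. Note
the standard-deviation pooling at work: `navy`, whose mean color is
*closest* to the sea, ranks worst because its difference map is the most
uneven — see the methods vignette
(`vignettes/camoscore-methods.Rmd`) for why, and for the
`include_mean` option.

Real image files work the same way through `run_compute()` / a YAML
config, or from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","camoscore.R",package="camoscore"))') \
    pair camo.png background.png --spd 35 --out result.json
```

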