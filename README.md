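# mmpsos

Detection and segmentation of regions of interest — typically nuclei — in
H&E-stained histopathology images, by **multiobjective particle-swarm
multilevel thresholding fused with superpixel clustering** (MMPSO-S).

In H&E imagery, hematoxylin stains nuclei dark purple and eosin stains
stroma pink, so the objects of interest are the dark intensity class. The
package searches for two intensity thresholds `(t1, t2)` that are jointly
good under three classical criteria, all maximised over the histogram of
the pre-processed (grayscale + CLAHE) image:

- **Otsu between-class variance** `f1 = Σ ω_r (μ_r − μ_T)²`
- **Kapur entropy** `f2 = Σ_r −Σ_i (P_i/ω_r) ln(P_i/ω_r)`
- **Renyi entropy** `f3 = Σ_r (1/(1−α)) ln Σ_i (P_i/ω_r)^α`

A multiobjective PSO evolves candidate threshold pairs, keeping an external
Pareto archive (capacity 30) with an adaptive hypercube grid; swarm leaders
are drawn by roulette over cube fitness `x/occupancy`, which steers the
search toward sparse parts of the front. The final thresholds come from the
archive member farthest from the objective-space origin,
`d(O,i) = sqrt(f1² + f2² + f3²)`. The dark class `I1 = [0, t1−1]` is then
united with a SLIC-style superpixel map (distance
`Dm = dRGB + (p/S)·dXY`, clusters kept when their mean pre-processed
intensity is below `t1`), and the merged mask is cleaned by hole filling,
morphological smoothing and small-component removal.

A synthetic-fixture generator (dark elliptical nuclei on pink stroma, and
trimodal Gaussian-mixture images with analytic valley thresholds) provides
exact ground truth, so the whole pipeline is testable without external
datasets.

## Worked example

```r
library(mmpsos)

# a 128x128 synthetic H&E-like field with 12 nuclei and exact ground truth
fx  <- make_nuclei_image(seed = 42)
seg <- run_pipeline(fx$image, seed = 42)
seg
#> MMPSO-S segmentation
#>   thresholds: t1 = 122, t2 = 198
#>   superpixels: 961 clusters
#>   archive size: 30
#>   foreground: 3432 px (20.9%)

segmentation_metrics(seg$mask, fx$mask)
#> TP 3389  FP 43  FN 10
#> precision 0.9875  recall 0.9971  F 0.9922  Dice 0.9922  Jaccard 0.9846
```

`t1 = 122` separates the dark (nucleus) class of the CLAHE-enhanced image;
the final mask overlaps the true nuclei with Dice 0.99 on this
high-contrast fixture. Threshold recovery can be checked against an
analytically known answer:

```r
tm  <- make_trimodal_image(seed = 7)     # modes 40/128/215, sd 8
res <- run_mmpso(tm$image, swarm_config(seed = 7))
res
#> Multiobjective swarm threshold search
#>   thresholds: 85, 172
#>   best fitness (otsu, kapur, renyi): 5105.92, 10.498, 10.0393
#>   archive size: 30
tm$valleys
#> [1]  84.0 171.5
```

The recovered thresholds sit on the analytic density valleys of the
mixture. `exhaustive_thresholds()` provides the brute-force reference for
small instances, and `segmentation_metrics()` / `detection_metrics()`
evaluate masks and centre detections (pixel Dice/Jaccard/F-measure;
greedy one-to-one centre matching).

A thin command-line front end is installed at
`inst/scripts/mmpsos-cli.R` with `segment`, `evaluate` and
`make-fixtures` subcommands; configuration files are YAML with the tuned
defaults (`load_config()` / `save_config()`).

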