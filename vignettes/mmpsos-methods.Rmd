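---
title: "Swarm-optimised multilevel thresholding with superpixel fusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm-optimised multilevel thresholding with superpixel fusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmpsos)
```

## The problem

In H&E-stained histopathology, hematoxylin renders nuclei dark purple while
eosin renders cytoplasm and stroma pink. Regions of interest — nuclei, or
specific immune-cell classes — are therefore the *dark* intensity class of
the image, and a large share of the segmentation problem reduces to finding
good intensity thresholds. A single threshold criterion (Otsu's
between-class variance, Kapur's entropy, Renyi's entropy) has known failure
modes on skewed stain distributions; this package searches for thresholds
that are good under all three criteria at once, then stabilises the
resulting mask with a superpixel stage that operates on colour rather than
intensity.

## The threshold model

For a 256-level histogram with probabilities $P_i = n_i/n_p$, $k$
thresholds $t_1 < \dots < t_k$ split the levels into $k+1$ regions, region
$r$ covering $[t_{r-1}, t_r - 1]$ (with $t_0 = 0$ and the last region
ending at 255). Each region has mass $\omega_r$ and mean $\mu_r$, with
$\sum_r \omega_r = 1$ and $\sum_r \omega_r \mu_r = \mu_T$ as exact
identities (these are asserted in the test suite). The three maximised
objectives are:

* **Otsu** $f_1 = \sum_r \omega_r (\mu_r - \mu_T)^2$ — between-class
  variance;
* **Kapur** $f_2 = \sum_r -\sum_i \frac{P_i}{\omega_r}
  \ln \frac{P_i}{\omega_r}$ — summed Shannon entropy of the
  region-normalised distributions;
* **Renyi** $f_3 = \sum_r \frac{1}{1-\alpha} \ln \sum_i
  (P_i/\omega_r)^\alpha$ — the one-parameter generalisation of $f_2$,
  recovering it as $\alpha \to 1$ (a property test checks
  $|f_3(\alpha = 1 \pm 10^{-4}) - f_2| < 10^{-2}$).

Empty regions contribute 0 to every objective rather than raising an
error: the swarm may propose degenerate threshold pairs mid-search and the
search space must stay total. The Renyi order is not fixed by the method;
we default to $\alpha = 2$ (quadratic entropy), exposed in the
configuration.

## The multiobjective swarm

The three objectives are genuinely conflicting, so the search is Pareto
rather than scalarised. Each particle carries a position
$X_i = (x_1, x_2)$ (real-valued thresholds in $[0, 255]$), a velocity in
$[-5, 5]$, and a personal best. Velocities start at zero; updates follow

$$V' = \omega V + c_1 r_1 (\mathit{pBest} - X) + c_2 r_2 (L - X), \qquad
X' = X + V'$$

with inertia $\omega = 1.3$, $c_1 = c_2 = 0.5$, $r_1, r_2 \sim U(0,1)$ per
particle, and the leader $L$ drawn from the external archive. Velocities
and positions are clamped (saturation, not reflection) to their ranges,
and the position components are sorted after each update so the pair is
always a valid threshold vector — the simplest contract that keeps every
particle feasible.

The external archive holds up to 30 mutually non-dominated solutions.
Candidates are inserted under the standard four rules (empty → insert;
dominated → discard; non-dominated with space → insert, evicting members
the candidate dominates; non-dominated at capacity → first remove one
member of the most crowded hypercube). Crowding is measured on an adaptive
grid: the occupied bounding box of archive fitness values is split into 7
divisions per objective, and leader selection runs a roulette wheel over
cubes with fitness $x/\text{occupancy}$ ($x = 10$; any $x > 1$ yields the
same probabilities after normalisation), then picks uniformly within the
chosen cube. This biases leaders toward sparse parts of the front. One
implementation note: candidates whose fitness vector exactly equals an
existing member's are discarded, preventing duplicate archive entries on
fitness plateaus (see below).

Mutation uses the canonical decreasing schedule
$p_m(t) = (1 - (t-1)/(N_{ite}-1))^{5/\mu}$ with $\mu = 0.1$: every
particle is eligible at $t = 1$, none at $t = N_{ite}$. A mutated particle
has one component redrawn uniformly in a window of half-width
$p_m \cdot 255/2$ around its current value, clamped to the range; the
window shrinks as the schedule decays, which matches the qualitative
contract (broad exploration early, local perturbation late). The exact
range-shrinking law is a design choice; only the decreasing-coverage
behaviour is fixed by the method.

After the final iteration the reported solution is the archive member with
the largest Euclidean distance $d(O, i) = \sqrt{f_1^2 + f_2^2 + f_3^2}$
from the objective-space origin. Defaults are 150 particles and 150
iterations, values tuned for H&E imagery; the package's unit tests use
smaller swarms (40 x 60) because the oracle-equivalence properties they
check converge long before that.

### Numerical choice: plateau-centred extraction

All three objectives depend on the threshold only through which *occupied*
histogram bins fall on each side. Moving a threshold across a run of empty
bins changes nothing, so on images with well-separated populations the
optimum is a plateau, and any point of it is an equally valid maximiser.
Reporting the first or a random plateau point makes the result an artifact
of enumeration order. We therefore re-centre each extracted threshold to
the midpoint of its fitness-tie plateau (scanning one component at a time
while the fitness vector is bit-identical), the same convention as
averaging tied optima in classical Otsu thresholding. On a trimodal
mixture this makes the reported threshold the maximum-margin cut of the
inter-mode gap, which is also where the analytic density valley lies. The
exhaustive search utility applies the same convention so the two routes
remain comparable.

## Superpixels and fusion

The colour route clusters the RGB image with a SLIC-style local k-means.
Centres start on a regular grid with spacing $S = \sqrt{n_p/n_c}$ — the
spacing that makes the expected cluster population $n_p/n_c$; using the
pixel count itself as a distance would be dimensionally wrong. With
$\lfloor H/S \rfloor \times \lfloor W/S \rfloor$ initial centres the
realised cluster count never exceeds the requested $n_c$ (default 1000,
suited to frames where nuclei are small). Pixels are assigned within
$2S \times 2S$ windows by $D_m = d_{RGB} + (p/S)\, d_{XY}$ (compactness
$p = 10$ on the 0–255 colour scale); centres are recomputed as member
means; empty clusters are dropped; iteration stops when the summed centre
displacement falls to $E \le 1$ or after 10 passes (SLIC's usual
convergence horizon). No connectivity enforcement pass is applied. Cluster
refinement then keeps whole clusters whose mean *pre-processed* intensity
falls below the dark threshold $t_1$ — the pre-processed image is used
because $t_1$ was derived from its histogram.

The refined superpixel mask is united (pixelwise OR) with the dark
threshold class $I_1$; union is the reading consistent with the stage's
purpose of adding whole-cluster support to ragged threshold boundaries.
Post-processing then (1) fills enclosed holes, (2) smooths edges with a
morphological opening-then-closing (disk radius 2 px), and (3) removes
8-connected components under 30 px. The order matters and is tested: a
thin ring whose filled area exceeds the cutoff must survive. Hole filling
and smoothing use EBImage; component labelling is an in-package
8-connected labeller (EBImage's is 4-connected).

## Pre-processing

Images are converted to grayscale with BT.601 weights
(0.299, 0.587, 0.114) — the method itself does not fix the weights, so we
adopt the common imaging default — then contrast-enhanced with CLAHE
(normalised clip limit 0.01, 8 x 8 tiles; both exposed). All intensity
computations downstream (histogram, threshold maps, cluster refinement)
operate on the CLAHE output. The threshold search adapts to whatever
histogram CLAHE produces, so results depend only weakly on the exact
CLAHE settings.

## What the synthetic fixtures emulate — and what they do not

`make_nuclei_image()` generates dark, purple-tinted ellipses
(mode 80, sd 10) on pink stroma (mode 190, sd 10) with additive noise
(sd 5): a well-stained, high-contrast H&E field with non-overlapping
nuclei and exact ground truth. `make_trimodal_image()` draws pixels
i.i.d. from a three-Gaussian mixture — default modes (40, 128, 215),
common sd 8, equal weights — and returns the analytic density-valley
thresholds. Its default size is $1000 \times 1000$ ($10^6$ pixels):
with far fewer pixels the inter-mode tails of this mixture are empty over
a ~25-level span and the valley position is simply not identifiable from
the histogram, by any method.

Passing on these fixtures demonstrates the mechanics — objective
computation, Pareto bookkeeping, convergence to exhaustive optima,
pipeline fusion — under conditions where the right answer is known. It
does **not** demonstrate performance on real tissue: real H&E exhibits
stain variation, touching and overlapping nuclei, chromatin texture,
out-of-focus regions and class imbalance, none of which the generators
model. Instance separation of touching nuclei is explicitly out of scope.

## Problem sizes used in the checks

The test suite and the acceptance script run, by design, at desk scale:
single-threshold oracle equivalence on 64 x 64 two-population images (the
swarm must equal the exhaustive Otsu scan exactly); multiobjective
optimality on 64-level rebinned histograms where the full
$\binom{63}{2}$ grid is enumerable; valley recovery on the
$10^6$-pixel trimodal fixture; and the full pipeline on 128 x 128 nuclei
fixtures with the default 150 x 150 swarm and ~1000 superpixels. These
sizes exercise every code path at full default parameters while each
individual check completes in seconds.

## Known limitations

* Thresholding is global: spatially varying stain intensity is handled
  only to the extent CLAHE normalises it.
* The archive's duplicate-fitness rejection means plateaus are represented
  by a single member; diversity on the front is measured in objective
  space only.
* $k = 2$ is the tuned regime; larger $k$ is supported by the types but
  untuned.
* The superpixel stage omits the connectivity enforcement of classic SLIC;
  labels are usually but not necessarily spatially contiguous.
* Centre-level detection matching is greedy nearest-first within a radius
  (default 8 px); it is not an optimal bipartite assignment, though the
  two rarely differ at realistic densities.
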