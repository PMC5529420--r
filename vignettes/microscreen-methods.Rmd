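---
title: "Methods: quantifying drug response in 3D microtissue co-culture images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying drug response in 3D microtissue co-culture images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microscreen)
```

# The analysis problem

Patient-derived tumor cells co-cultured with stromal fibroblasts in
extracellular matrix form complex 3D microtissues: compact multicellular
organoids (tumor) interlaced with a meshwork of thin, branching fibroblasts.
Confocal maximum projections of live-cell-stained wells are 8-bit grayscale
images with a dark background, foreground brightness that varies strongly
both within and between images, and content ranging from nearly empty to
nearly full wells.  The package turns such images into per-well, per-class
growth and morphology measurements and tests treatment effects against a
vehicle control.

The processing chain is: stitch the four per-well tiles → threshold the well
into foreground and background → set small round structures aside → split
the remaining foreground into ~350-px regions → classify each region as
tumor or fibroblast from texture features → split each class into structures
by watershed → summarize area, diameter, and roundness → rank-based
statistics per treatment and concentration.

# Thresholding by local entropy

Global intensity thresholds fail on these images because brightness is not a
reliable foreground cue.  Texture is: tissue neighborhoods contain many
distinct gray levels, flat background very few.  The standardized local
entropy of pixel $i$ is

$$e^*_i = \frac{-\sum_{v \in V} p_v \log_2 p_v}{\log_2 \#w_i},$$

where $V$ is the set of unique 8-bit values in the $7\times7$ window $w_i$
around $i$, $p_v$ their relative frequencies, and $\#w_i$ the number of
window pixels actually inside the image (windows shrink at borders, and the
normalizer shrinks with them, so $e^*_i \in [0,1]$ everywhere).  Intensities
are re-quantized to 256 levels before the filter so that "unique values" is
well defined; entropy is then invariant to the local and global brightness
of the image, which is exactly the property the heterogeneous staining
demands.

A global threshold (Otsu's variance criterion by default; Tsai's
moment-preserving threshold as the alternative) is applied to the entropy
image, followed by four corrections:

1. **Bright-pixel rescue** — pixels with original intensity above 0.2 are
   always foreground.  Very bright *and very smooth* organoid interiors have
   low entropy and would otherwise be lost; brightness above this
   conservative level is unambiguous tissue.
2. **Topology-preserving thinning** — the entropy filter marks a pixel as
   soon as its window touches texture, dilating every object by up to half a
   window.  We peel up to 3 one-pixel layers (half the 7×7 window), removing
   a pixel only if it is a *simple point*, i.e. if removal changes neither
   the number of 8-connected foreground components nor the number of
   4-connected holes.  The peel is additionally depth-limited (pass $k$ may
   only remove pixels at Chebyshev depth $k$ of the input mask), so thinning
   can never eat into an object by more than the dilation it corrects.
3. **Debris removal** — components with a maximum (Feret) diameter under
   10 px are deleted.
4. **Hole filling** — enclosed background holes under 100 px are filled.  A
   hole is only filled when its surrounding foreground is a single
   component, so filling can never merge two structures.

One guard is added for degenerate inputs: a parameter-free global threshold
always splits its histogram somewhere, so on a well with no tissue the
nominal "foreground" class is merely the brighter half of the noise.  Since
tissue is bright on a dark background, the candidate foreground must exceed
the background by at least `min_foreground_contrast = 0.02` in mean original
intensity; otherwise the thresholding step returns an empty mask (rescue
still applies).  On textured wells the observed contrast is an order of
magnitude larger, so the guard only fires on empty wells.

Mask quality is scored against (possibly averaged, hence continuous) expert
reference masks with the continuous false-positive and false-negative rates

$$\mathrm{FPR} = \tfrac1N \sum_i (f_i - r_i)_+, \qquad
  \mathrm{FNR} = \tfrac1N \sum_i (f_i - r_i)_-,$$

the average amounts of excess and missing foreground; on binary inputs these
reduce to FP/N and FN/N, and their sum is the mean $L_1$ distance.

# Regions, features, classification

Small round structures (Feret diameter < 30 px, roundness ≥ 0.5) are
dead or dying cells of either type; they are reported as a third class and
excluded from texture classification.

The remaining foreground is partitioned into regions of roughly 350 px — the
scale of one large cell or a small multicellular structure, big enough to
carry texture, small enough to trace class boundaries.  Seeds sit on a
hexagonal lattice whose Voronoi cells have the target area; each foreground
component that misses the lattice gets one seed at its interior-most pixel.
Regions grow from the seeds by geodesic distance *within the mask* (the
propagation is run with a constant intensity image, so only the seeds and
the mask geometry shape the regions, and no region ever crosses a
background gap).  Clipped remnants under 20 px merge into their largest
neighbor, as texture statistics on a handful of pixels are meaningless.

Each region yields 37 features:

* standardized entropy of the region's 8-bit values (entropy / $\log_2$ of
  the region size), 1 feature;
* standard deviation of the pixel values, 1 feature;
* rotation-invariant uniform local binary patterns (8 neighbors, radius 1):
  patterns with ≤ 2 circular transitions are labeled by their number of set
  bits (9 labels); all non-uniform patterns share a tenth label that is
  dropped as redundant, leaving 9 relative frequencies;
* co-occurrence statistics: region intensities are min–max normalized and
  quantized to 32 gray levels, symmetric co-occurrence matrices are
  accumulated at distance 1 in the 4 canonical directions over pixel pairs
  that both lie in the region, and 13 classic statistics are summarized by
  their mean and range over the directions — 26 features.

All 37 are invariant to translation, reflection, and to brightness offsets
(entropy and LBP by construction, SD trivially, co-occurrence through the
per-region normalization), so classification cannot latch onto staining
intensity.  The 32-level quantization balances co-occurrence matrix
occupancy for ~350-px regions and is configurable.  Features are
standardized and reduced by PCA to the smallest number of leading components
reaching 95% explained variance — always data-driven, never a fixed count —
and the culture-method covariate is appended untouched.

Four classifier families are compared under stratified 10-fold
cross-validation: logistic regression; random forests (1000 trees,
$\sqrt p$ candidates per split, minimum terminal-node fractions from
{2.5%, 5%, 10%}); Gaussian-kernel SVMs with the kernel width set by the
pairwise-squared-distance quantile heuristic and cost from {1, 10, 100};
and a bundling ensemble that, in each of 20 bootstrap rounds, trains
logistic regression, 5-NN and 10-NN on the out-of-bag sample, feeds their
predictions as extra covariates to a decision tree on the in-bag sample,
and averages the 20 trees.  Families are compared by AUC; accuracy, F1 and
the common sensitivity/specificity value are reported at the decision
threshold that equalizes sensitivity and specificity, calibrated on pooled
out-of-fold scores and then frozen — neither class is favored, and
calibrating on pooled held-out scores avoids the optimistic bias of
in-sample calibration.  SVM scores are the logistic transform of the
decision values rather than Platt-calibrated probabilities: the ranking
(hence AUC and the equal-error threshold) is identical, and the scores are
exactly reproducible, which the pipeline's determinism contract requires.

Ground-truth region labels come from majority votes of expert class
paintings: tumor and fibroblast pixel votes are summed per region across
paintings, the larger total wins, and exact ties are excluded from
training.

# Morphometry and statistics

Each class mask is split into structures by the watershed transform of its
Euclidean distance map, which cuts necks that are narrow relative to the
structures they join.  Regional maxima within 2 px are merged before
flooding to suppress over-segmentation on distance plateaus; the narrow-neck
splitting this produces is mild by design and the merge radius is
configurable.  Rounded single cells bypass the watershed — each component is
one structure by definition.  Per structure we record the area $A$ (pixel
count), the maximum diameter $D$ (Feret diameter over the convex hull, plus
one pixel width so a single pixel has $D = 1$), and the roundness
$4\pi A/(\pi D)^2$ — 1 for a disc, decreasing toward 0 with elongation, a
proxy for epithelial differentiation versus invasion.

Treatment effects are tested against the pooled vehicle-control wells with
the two-sample Van der Waerden normal-scores test: pooled mid-ranks $r_i$
map to scores $\Phi^{-1}(r_i/(n+1))$ and the squared standardized difference
of group mean scores is referred to $\chi^2_1$.  The test keeps the
robustness of a rank test while retaining near-parametric efficiency under
normality, and its statistic is invariant under monotone transforms of the
data.  Below 15 observations per group the p-value is computed by exact
enumeration (or 10,000 Monte-Carlo permutations when enumeration is too
large), since the $\chi^2$ approximation is the only questionable step at
screening-plate group sizes.  Well-level endpoints (per-class total area,
rounded-cell count) use wells as observations; structure-level endpoints
(area, roundness of tumor structures) pool structures across the replicate
wells of a condition — the sampling unit is then the structure, and
within-well clustering is a documented caveat of those p-values.
Significance stars follow the 0.05/0.01/0.001 convention.

# The synthetic-data generator

No deposited image data exists, so every stage is validated on synthetic
wells with per-pixel ground truth.  The generator emulates the documented
characteristics of the real data: dark background (base level 0.015,
Gaussian noise SD 0.004 — about one 8-bit level, as after acquisition-side
background removal); organoids as elliptical blobs with a smooth radial
profile modulated by low-frequency multiplicative noise (±18%, smoothed at
σ = 3 px) plus fine additive texture (SD 0.015); fibroblasts as anti-aliased
random-walk strokes 2–4 px wide, usually with one branch, with brightness
varying along the stroke; rounded single cells as small discs (diameter
≤ 15 px); per-object peak brightness uniform on [0.35, 0.9] (several-fold
between-object variation); tumor precedence at overlapping pixels (then
fibroblast over single cell); and 8-bit quantization applied last, after
all noise.  Defaults (512×672 px, 8 organoids of radius 18–42 px, 14
fibroblasts of length 80–200 px, 25 single cells) give wells roughly 9%
covered; content can be driven from empty to dense through the parameters.

Simulated expert masks perturb the true foreground boundary: a smooth random
field (σ = 6 px) is added to the signed distance from the boundary and
re-thresholded at zero, so disagreement is boundary-localized
dilation/erosion.  Real expert-to-expert disagreement is only ever
characterized visually, so the magnitude (3 px × disagreement) is
calibrated by eye to produce the gray disagreement bands seen in averaged
expert masks at `disagreement ≈ 0.3–0.6`.

Plates apply per-treatment effects to the generation parameters before
rendering — a multiplicative organoid-area effect (radius × √effect), a
roundness shift (added to the axis-ratio range), and a rounded-cell rate —
scaled linearly with concentration up to the treatment's maximum.

What the generator does *not* emulate: confocal point-spread blur, z-stack
artifacts, uneven illumination fields, matrix autofluorescence, or textures
whose classes differ more subtly than "smooth blob vs edge-rich stroke".
Passing tests therefore demonstrate that the chain is implemented correctly
and recovers known truth under the stated image model — not that the
classifier's accuracy transfers to any particular microscope's data.  The
analysis of real experiments should retrain the classifier on
expert-painted regions from the same experiment, exactly as the screening
workflow intends.

# Numerical choices and degenerate inputs

* All histogram computations use the 256-level 8-bit grid; thresholds are
  multiples of 1/255 and the foreground rule is strict (`pixel > t`).
* Foreground connectivity is 8, background/hole connectivity 4 — the
  standard duality that keeps hole filling and thinning consistent.
* A constant image has no Otsu or Tsai threshold (error); a constant
  *region* yields the defined feature fallbacks (entropy 0, SD 0, LBP mass
  on the all-equal code, co-occurrence energy 1 and all else 0).
* Feret diameters use the convex hull, so they are exact and cheap even for
  large structures.
* Stitching is integer-pixel only (phase-correlation peak, wrap ambiguity
  resolved by the candidate placement with the best overlap correlation);
  overlapping pixels keep the earlier tile in raster order.  Interpolation
  or averaging would blur the 8-bit texture the classifier depends on.
* Identical seeds give bit-identical plates, masks, tables and test
  results; every stochastic step (generation, fold assignment, bootstrap,
  permutation) draws from R's RNG under a caller-supplied seed.

# Validation problem sizes

The test suite exercises thresholding at the full default well size
(512×672); classification, partitioning and pipeline tests run on 224×288
wells with 3 organoids, 8 fibroblasts and 8 single cells (and 192×256 for
the 6-well demo plate), which preserves the object scale — only the field of
view shrinks.  The classification validation trains on 20 such wells and
tests on 10 held-out wells; statistical calibration uses 500 null
simulations and a 10,000-draw permutation oracle.

# Known limitations

* The equal-error threshold is calibrated on pooled out-of-fold scores;
  with very small training sets its variance is appreciable.
* Structure-level p-values treat structures as independent; wells are the
  true experimental unit and a conservative reading should lean on the
  well-level endpoints.
* The watershed merge radius (2 px) suits organoid-scale structures; very
  elongated fused structures may still over-split.
* Bundling's out-of-bag base learners can be trained on few points in small
  data; degenerate resamples fall back to the full sample for that round.
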