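---
title: "Quantifying protein clustering, colocalization and spine morphology along dendrites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein clustering, colocalization and spine morphology along dendrites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brightclust)
```

## The measurement problem

Membrane-deforming proteins such as the I-BAR/MIM family member ABBA
concentrate into micrometre-scale *brightness clusters* on dendritic
membranes of cultured neurons, and those clusters are candidate initiation
sites for new dendritic protrusions. Quantifying this requires a chain of
image measurements: restrict attention to a single dendrite in a crowded
field, decide which pixels are "bright", merge nearby bright pixels into
clusters, and express the clustered area per micrometre of dendrite so that
neurons with different dendrite lengths are comparable. Around that core
sit three companion measurements: pixel-intensity colocalization between two
channels (does the protein sit where a phosphoinositide marker sits?),
membrane-versus-diffuse and transfected-versus-untransfected intensity
ratios, and dendritic-spine morphometry (thin/stubby/mushroom counts per
micrometre).

This package implements that chain end to end and pairs it with a seeded
synthetic-scene generator, so every stage can be validated against planted
ground truth without access to raw microscopy data.

## Observation paths

A dendrite of interest is traced by hand as a 1-pixel-wide white curve on a
black background (a *skeleton curve*). The ROI used for all cluster
measurements — the *observation path* — is that curve grown to both sides by
a fixed radius, 95 px by default, giving a 191-px-wide band for a straight
curve. We implement the grow step as Euclidean disk dilation (all pixels
within distance `r` of the curve): it reproduces the 191-px width exactly
for straight curves, is monotone in the radius, and has an unambiguous
definition at curve corners, whereas drawing-tool "grow selection"
implementations vary by version. The mask is clipped at image borders
without error, since real dendrites routinely leave the field of view.

Dendrite length is measured on the skeleton itself by walking its
8-connected pixel graph: orthogonal steps count 1 px, diagonal steps
\(\sqrt 2\) px, branches are summed. We compute this as the minimum
spanning tree weight of the pixel graph, which visits every pixel once and
ignores the spurious diagonal shortcut edges that 8-adjacency introduces at
corners; a loop's closing edge is dropped, so loops are counted once. At
the calibration used for cluster images (5/95 µm/px), a 96-pixel straight
skeleton measures exactly 5 µm.

## Brightness clusters: global and adaptive thresholding

All thresholds operate on a normalized brightness scale: integer images are
divided by their dtype maximum (`2^bit - 1`), never by the image's own
maximum, so a threshold of 0.4 means the same physical brightness in every
image.

The pipeline is

1. maximum-intensity projection per channel (each output pixel the maximum
   over z),
2. Gaussian smoothing with an explicit square kernel (side 51 px, σ = 0.8 px
   by default) — the smoothing agglomerates separate but closely positioned
   bright pixels into a single region,
3. a bright-pixel criterion, either
   * **global**: `value >= 0.4` (one minimum brightness for the whole
     image), or
   * **adaptive**: `value >= mean(window) + offset`, with the window a
     21 × 21 px rectangle centred on the pixel (half-size 10), clipped at
     image borders,
4. connected-component labeling (8-connectivity by default) restricted to
   the observation path, and conversion of areas to µm² and to µm² per µm
   of dendrite.

The adaptive criterion exists because confocal fields vary in exposure,
focus and composition: a fixed global threshold that is right for one image
is wrong for another, and within one image a shading gradient can push an
entire region above or below it. Because the adaptive criterion is relative
to the local mean, adding a constant to the whole image leaves its mask
unchanged — a property the test suite asserts exactly — while the global
mask is deliberately not shift-invariant. The generator's
"linear-gradient" background (0 → 0.5 across the image) is built to make
this concrete: the gradient crosses 0.4, so global mode reports a spurious
cluster on an empty scene and merges or misses planted puncta, while
adaptive mode recovers every planted count.

Choices worth stating explicitly:

* The threshold is applied to the **smoothed** image and the components of
  that mask are the clusters; the raw image is not re-consulted. The
  smoothed image is what defines brightness regions; a
  `require_raw_bright` flag optionally demands one raw bright pixel per
  region for users who want the stricter reading.
* Comparisons are inclusive (`>=`), making the printed value a true
  minimum.
* The window mean includes the centre pixel, and border windows average
  over the available pixels only; shift-invariance holds exactly under both
  conventions.
* The 51-px kernel with σ = 0.8 is implemented literally even
  though the effective support of such a narrow Gaussian is ≈ 5 px; the
  kernel is renormalized to unit sum after truncation, so constant images
  are fixed points of the smoother.
* The adaptive offset is deliberately analyst-selected per experimental
  setup; 0.1 is a neutral default, and comparisons should always use one
  offset within a shared setup.

For live-imaging series, `normalize_timeseries()` divides each frame's
total cluster area by the mean of the four frames preceding treatment, so
each neuron serves as its own baseline and the post-treatment values can be
tested against the hypothetical value 1.

## Colocalization and intensity ratios

`pcc()` is the Pearson correlation of paired pixel intensities of two
maximum-intensity projections within an ROI mask: +1 full colocalization,
0 no relation, −1 mutual exclusion. A channel that is constant within the
ROI has no defined correlation; we raise an error rather than report 0,
because silently coding "undefined" as "uncorrelated" biases group means.
No background floor is applied within the ROI — every ROI pixel enters the
correlation.

`membrane_diffuse_ratio()` works on a single mid-dendrite focal plane:
1-px lines along both dendrite edges (plasma membrane) and one line along
the middle (diffuse pool) are averaged, and the ratio is mean(membrane
means) / centre mean. Lines are sampled at the nearest pixel with no
sub-pixel interpolation, matching line-mean semantics of standard image
software at this scale. The ratio is invariant under global multiplicative
intensity changes, so it is comparable across acquisition settings.

`expression_ratio()` compares mean intensity in an ROI over
construct-expressing cells to an ROI over untransfected cells in the same
image; if the construct does not perturb the measured stain the expected
ratio is 1.

## Spine retention and classification

Protrusion measurements (from any 3D morphometry tool, or from this
package's 2D measurement routine) pass a retention filter: volume ≥ 0.020
µm³, length between 0.1 and 5 µm, maximal width ≤ 3 µm, all boundaries
inclusive. Retained spines are classified in a fixed order: **mushroom**
if head diameter ≥ 0.35 µm *and* head/neck ratio ≥ 1.1; otherwise
**stubby** if volume ≥ 0.040 µm³; otherwise **thin**. The µm³ thresholds
are the authoritative contract — voxel-count equivalents depend on the
voxel size and are derived from it via `voxel_volume_um3()` (at the
0.066 × 0.066 × 0.2 µm voxel of the spine stacks, 0.020 µm³ is 23 voxels).
A zero neck with a nonzero head leaves the ratio undefined and errors
rather than guessing. Densities are counts per µm of dendrite, total and
per class, and the classes partition the retained set by construction.

`measure_protrusions()` provides a transparent 2D measurement convention
for synthetic scenes: protrusion pixels are binned by Euclidean distance to
the dendrite shaft; each bin is a chord perpendicular to the protrusion
axis; length is the maximal distance, the head diameter the largest chord
in the distal half, the neck the smallest chord between base and head, and
volume is pixel area × a nominal section thickness (0.2 µm). This is a
desk-scale stand-in for 3D surface modeling, not a reimplementation of it;
border-touching protrusions are flagged and excluded rather than measured
wrongly.

## The synthetic-scene generator

The generator is the package's substitute for raw data and defines the
conditions under which the pipeline is validated:

* **Puncta scenes** — isotropic Gaussian spots (truncated at 3σ) with
  pairwise-disjoint supports at least 2 px apart, on flat, linear-gradient
  or low-frequency backgrounds. "True area" is the pixels above
  half-maximum, which makes planted area unambiguous; the stated radius is
  the half-maximum radius. Defaults (256² px, peak 0.8 above a 0.1
  background, noise off) put scenes firmly in the regime where counts are
  recoverable, and the recovery tests sweep 0–25 puncta.
* **Correlation pairs** — `chanB = ρ·S + sqrt(1−ρ²)·N` with `S` the
  standardized first channel and `N` independent standardized noise; the
  limits ρ = ±1 are exact and the sample correlation fluctuates around ρ
  with the usual \((1-\rho^2)/\sqrt n\) error, which the recovery tests
  average over 100 seeds.
* **Membrane scenes** — a dendrite band with 1-px edge lines whose
  pre-noise mean is exactly `enrichment` × the centre-line mean.
* **Protrusion tables and images** — descriptors sampled strictly inside
  each class region (≥ 5% margin from every boundary), plus optional
  retention-violating rejects; rendered templates (narrow pegs, wide
  rectangles, ball-on-stick) drawn at 0.02 µm/px so a 0.35-µm head spans
  ~18 px and rasterization cannot flip a class.

Noise is additive Gaussian clipped to [0, 1]; Poisson photon statistics,
PSF blur and detector artefacts are deliberately not modeled — no noise
model is part of the measurement definitions, and the tests are about the
measurement chain, not about acquisition physics. Passing recovery tests
on these scenes therefore demonstrates correctness of the algorithms under
controlled conditions, not performance on real micrographs; the adaptive
offset in particular still needs per-setup human selection on real data.
All generators take one explicit integer seed per call, restore the session
RNG state, and are bit-identical under the same seed.

## Group statistics

`compare_groups()` covers the comparisons used with these metrics: Welch
two-sample *t*-test by default (the safer choice under unequal variances;
pooled-variance available), Mann–Whitney U, Wilcoxon signed-rank against
the hypothetical value 1 for baseline-normalized series, and
Kruskal–Wallis; `anova_two_way()` fits factorial designs with Type II sums
of squares. The Mann–Whitney p-value is computed by exact enumeration over
all group assignments whenever the smaller group has ≤ 8 observations
(midranks handle ties), and by the tie-corrected normal approximation
otherwise; the signed-rank test enumerates all 2ⁿ sign patterns for n ≤ 15.
Exact small-sample enumeration matters here because per-figure group sizes
in this kind of experiment are often below 10, where the normal
approximation is visibly wrong. The test suite cross-checks the exact
routes against independent brute-force permutation enumeration and against
`stats::wilcox.test` on tie-free data, and verifies the type-I error rate
under the null within binomial bounds.

`run_experiment()` ties the stages together: a config (R list or YAML)
names groups, per-group generator settings and metrics; each neuron gets a
derived seed; the result is a tidy (neuron, group, metric, value) table
with a provenance attribute (config, seed, config hash) so a rerun is
reproducible bit for bit.

## Worked example

```{r example}
cal <- calibration(5 / 95)
scene <- make_puncta_image(scene_params(n_puncta = 12, punctum_peak = 0.8,
                                        background = "linear-gradient"),
                           seed = 42)
sk <- matrix(FALSE, 256, 256); sk[128, ] <- TRUE
roi <- grow_skeleton(skeleton_curve(sk, cal), radius_px = 95)
roi

run_cluster_pipeline(scene$image, roi, cluster_params("adaptive"))
run_cluster_pipeline(scene$image, roi, cluster_params("global"))
```

Of the 12 planted puncta, 8 fall inside the 191-px observation path and 2
more straddle its edge; the adaptive mode reports exactly those 10 as
clusters. The global threshold instead reports 7 regions covering over
30 µm² — the bright end of the gradient background itself crosses 0.4 and
swamps the real puncta.

## Numerical choices and limitations

* Problem sizes throughout the examples and tests (256–320 px scenes,
  ≤ 25 puncta, 100-seed correlation averages, 1000-simulation null
  calibration) were chosen as the smallest sizes at which the statistical
  assertions have comfortable margins.
* Cluster labels are numbered in raster order of first occurrence, so
  labelings are deterministic.
* `label_clusters` treats the ROI restriction as a hard mask: a cluster
  partially inside the path contributes only its inside pixels.
* The 2D protrusion measurement assumes protrusions roughly perpendicular
  to the shaft; strongly recurved spines would need the 3D route.
* Degenerate inputs fail loudly by design: empty skeletons, constant
  channels within an ROI, zero baseline means, zero necks with nonzero
  heads, over-dense puncta requests.
* The repository is organised as an analysis workflow: numbered drivers
  under `analysis/` narrate the standard runs and write tables under
  `results/`, while all computation lives in the package so the tests and
  the acceptance script exercise exactly the code the drivers use.
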