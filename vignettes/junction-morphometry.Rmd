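---
title: "Junction morphometry: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction morphometry: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctmorph)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite does not itself compute.

## The measurement model

VE-cadherin immunofluorescence in lymphatic endothelium appears as discrete
fragments: elongated segments along cell borders (continuous in "zipper"
junctions, short and gapped in "button" junctions of initial lymphatics) and
small round puncta associated with VE-cadherin internalization and turnover.
The pipeline turns a calibrated single-channel image into per-fragment shape
descriptors, per-field category percentages, and per-cell junctional
coverage statistics.

### Segmentation (`segment_fov`)

Fields are tiled into **20 × 20 µm blocks** (edge blocks smaller) and each
block is thresholded independently, which adapts to slow illumination
gradients. The threshold is Otsu's between-class-variance maximizer with two
guards:

* blocks whose dynamic range is below `range_epsilon` (default 0.5 intensity
  units; a noise-only block spans roughly 8 standard deviations of the
  noise) are declared empty — Otsu always "finds" a threshold, even in pure
  noise;
* the threshold is floored at `min + floor_frac × range` with
  `floor_frac = 0.45`. Otsu is unreliable when foreground occupies well
  under 1% of a block (it then splits the background mode); the floor sits
  near the half-maximum of a blurred object, which is also where an edge of
  a Gaussian-blurred structure reproduces the true object outline most
  faithfully. `floor_frac` was tuned once against ground-truth masks
  (median recovery Jaccard across seeds) and then frozen; the regression
  test requires ≥ 95% of true fragments recovered at Jaccard ≥ 0.7 under
  the default noise and blur.

Components are 8-connected; objects under `min_area_px = 3` pixels are
discarded. Objects split by block borders stay split — the per-block
procedure implies it — and carry a border-touching flag so users can exclude
or re-merge them in sensitivity analyses. Accuracy bookkeeping against
synthetic truth therefore scores each true structure by its *dominant*
measured piece (`match_truth_to_measured`).

### Shape descriptors (`shape_table`)

* **Circularity** `4πA/P²`, the particle-analysis standard, clipped to
  [0, 1]. The perimeter estimator matters: raw crack-length (pixel-edge
  counting) is biased high by up to 4/π on diagonal boundaries, making even
  perfect disks read ~0.62. We trace the outer boundary (Moore
  neighbourhood) and apply the Vossepoel–Smeulders corner-corrected
  chain-code estimator, `0.980·N_even + 1.406·N_odd − 0.091·N_corner`, plus
  π for the outward half-pixel offset of a convex outline (the chain
  measures the pixel-center polyline; Minkowski offset by half a pixel adds
  `2π·½`). Digitized disks of radius ≥ 5 px then measure circularity
  within 0.05 of 1, and the estimate is stable (±2%) under resolution
  doubling. The raw crack mode is kept because it is *exact* for
  axis-aligned rectangles, giving an analytic oracle.
* **Aspect ratio**: the major/minor axis-length ratio of the
  second-central-moments ellipse — rotation-invariant, unlike bounding-box
  ratios. The minor axis is floored at one pixel so single-pixel objects are
  defined (AR = 1).
* **Length**, two modes. `major_axis` is the *maximum caliper (Feret)
  diameter* plus one pixel of end caps. We deliberately do not use the
  moments-ellipse major axis here: for a uniform rod it reads 1.155 L and
  for a disk 0.87 d, whereas the caliper returns the rod length, the disk
  diameter, and the chord of a curved arc — the behaviour a length report
  should have. `skeleton` is the geodesic diameter of the Zhang–Suen
  skeleton plus one pixel, measured by shortest paths on the skeleton graph
  (1 / √2 step weights); shortest paths rather than adjacency sums avoid
  over-counting staircase corners. The skeleton follows curvature, so it is
  the default for coverage sums along curved junctions; its known bias is a
  retraction of about half a width at each end of wide objects (a 7 × 0.5 µm
  bar reads ≈ 6.6 µm).

### Classification (`classify_fragments`)

Four categories from the joint (aspect ratio, circularity) bins:

| category | aspect ratio | circularity |
|---|---|---|
| 1 | above Q3 | 0–0.25 |
| 2 | Q2–Q3 | 0.25–0.5 |
| 3 | Q1–Q2 | 0.5–0.75 |
| 4 | below Q1 | 0.75–1 |

Categories 3–4 capture the short round fragments attributed to VE-cadherin
turnover; categories 1–2 the elongated junctional segments. Three choices
the category definition leaves open are surfaced as configuration rather
than guessed silently:

* **Quartile reference population** (`scope`): default is all fragments of a
  comparison cohort pooled. Between-group comparisons only make sense when
  both groups share bin boundaries; per-FOV quartiles are available for
  sensitivity analysis.
* **Discordant joint bins** (`mode`): a fragment can satisfy the circularity
  condition of one category and the aspect-ratio condition of another. The
  default `lenient` mode assigns by circularity and flags the discordance
  (reported as a rate), because per-FOV percentages are computed on the
  *total* fragment count — every fragment must be counted. `strict` mode
  labels such fragments unclassified; they stay in the denominator and are
  reported separately, so percentages always sum to 100.
* **Edge conventions**: circularity bins are right-closed, circularity 0
  falls in bin 1, and aspect-ratio ties at a quartile fall in the lower-AR
  (higher-category) bin.

Aggregation is fragments → FOV → animal → group; comparisons run at the
animal level (per-animal means of FOV percentages) with the one-tailed
Wilcoxon rank-sum test, whose direction must be declared by the caller.

### Junction metrics (`junction_metrics`)

Coverage is `100 × Σ junctional fragment length / cell perimeter`; fragment
density is `100 × n / vessel length`; the length distribution is reported as
a right-continuous empirical CDF. A fragment is junctional when its centroid
lies within `tolerance_um` (default 1 µm, about two fragment widths) of the
cell perimeter polyline; each fragment belongs to at most one cell (its
nearest perimeter). Perimeters come from synthetic ground truth or an
annotation table — inferring cell outlines from the VE-cadherin channel
alone is out of scope, since gapped button junctions underdetermine them.
Coverage uses skeleton lengths by default (curved fragments), the CDF the
caliper length; both are recorded.

### Clearance kinetics (`fit_decay`)

Intensities are baseline-subtracted (tissue enhancement), normalized to the
first post-injection timepoint, and time is re-origined there — the only
reading under which "normalized fluorescence intensity = e^(−kt)" starts
at 1. The model is a **pure exponential with no plateau**; many "one-phase
decay" implementations add a plateau, but the stated model is the contract,
and a plateau term is available behind `plateau = TRUE` (off by default).
Least squares runs on the normalized scale (log-least-squares would
re-weight late timepoints); the log-linear slope only initializes the
search. The 1-D objective is minimized by Brent's method after a coarse
log-grid bracket — the objective flattens for large k, which can strand a
golden-section search on the plateau; `nls` is avoided because it fails on
zero-residual (noiseless) data, where the fit must recover k to six
decimals. Half-life is `ln(2)/k`.

### Statistics (`t_test`, `rank_sum_test`)

The t test is the Welch unequal-variance variant (the safer default when the
variant is unspecified; the choice is recorded in the result). The rank-sum
test enumerates all `choose(nA+nB, nA)` rank assignments exactly for
combined n ≤ 20 — valid under ties because enumeration is over the observed
mid-rank multiset — and otherwise uses the normal approximation with tie
correction and continuity correction. Exactness matters at per-animal sample
sizes (n = 5–7 per group), where the approximation is visibly off. No
multiple-testing correction is applied across the four categories by
default (per-category p-values are reported as such); `holm_adjust` exists
for sensitivity analyses. Note the exact test is discrete: at n = 6 + 6 its
attainable two-sided level just below 0.05 is ≈ 0.041, which is what a null
simulation converges to.

## The synthetic world

`scene_spec()` defaults state the world the tests run in: a 100 × 100 µm
field at 0.1 µm/px (the scale of a high-NA oil-immersion confocal
objective), 9 cells from
a Lloyd-relaxed Voronoi tessellation (two iterations — convex, roughly
isotropic cells of ~33 µm diameter, plausible for lymphatic endothelium; no
published cell-geometry statistics exist to fit against), 60 junctional bars
(3 ± 1 µm × 0.5 µm) and 30 pan-cellular puncta (1 ± 0.15 µm diameter),
Gaussian PSF σ = 0.2 µm, additive Gaussian noise σ = 0.05 of unit fragment
intensity, background 0.1.

Placement uses **edge ownership**: neighbouring cells share Voronoi edges,
and a junction interface is one biological structure, so each shared edge is
decorated exactly once (by the lower-indexed cell). Fragments are packed
within single straight edges (no corner overshoot) with at least
`min_gap_um = 0.4` µm between neighbours so rasterized objects remain
resolvable; requested loads exceeding the owned perimeter raise an error
naming the cell. Noise is additive Gaussian, not Poisson: the pipeline under
test is threshold-based, so photon statistics are irrelevant to its
contract. The generator labels every fragment with its intended class,
length, owning cell, and junctional flag, which is what makes classifier
accuracy and coverage measurable.

What the generator does **not** emulate — and hence what a green test does
not establish: uneven illumination and vignetting, structured background
(autofluorescence, out-of-focus light), Poisson photon statistics, curved
junction fragments (bars are straight), true oak-leaf (non-convex) cell
shapes, 3-D sectioning, and multi-channel context. Results on real images
depend on those factors; the tests certify the measurement chain, not the
microscope.

Every stochastic operation takes an explicit seed and restores the caller's
RNG state; identical specs reproduce bit-identical scenes, and the pipeline
writes byte-identical CSVs under a fixed seed.

## Degenerate inputs and numerical conventions

* Coordinates: origin top-left, x right, y down; pixel centers at
  half-integer µm positions; lengths in µm everywhere, pixels only at
  rasterization.
* Empty FOV → percentage error (not silent zeros); empty or uniform blocks
  → zero fragments, no error.
* Circularity above 1 from discretization is clipped; a zero-perimeter
  degenerate object is defined as circularity 1.
* Quartiles need ≥ 4 values; fits need ≥ 3 timepoints; a series whose first
  post-injection value does not exceed baseline is rejected as
  non-informative.
* All-tied rank-sum input reports p = 1 with a tie note rather than failing.

## Known limitations

* Skeleton lengths under-read wide objects by about one width; coverage of
  wide-bar scenes inherits a few percent of negative bias (the caliper mode
  is recorded alongside for exactly this reason).
* Per-block thresholding splits objects at block borders; counts are
  slightly inflated and length CDFs gain a short-fragment tail. The border
  flag and dominant-piece matching are the provided mitigations.
* The Voronoi mosaic is convex; real lymphatic endothelial cells interdigitate.
  Coverage and density metrics are insensitive to this; absolute perimeter
  lengths are not.
* The clearance model is a single compartment with a single rate; tissues
  with tracer re-entry or biphasic washout need a different model.
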