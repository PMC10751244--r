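# junctmorph

Quantitative analysis of VE-cadherin adherens-junction morphology in
lymphatic endothelium, plus tracer-clearance kinetics.

## The problem

Initial lymphatic vessels take up interstitial fluid through discontinuous
"button" junctions: short VE-cadherin fragments separated by gaps along the
borders of oak-leaf-shaped endothelial cells. Under inflammatory or tumor
challenge these remodel toward continuous "zipper" junctions, and increased
VE-cadherin turnover shows up as small round fragments (puncta) scattered
through the cell. Both transitions are visible in single-channel VE-cadherin
immunofluorescence, but scoring them by eye is slow and biased.

`junctmorph` provides the full measurement chain for whoever needs these
readouts from calibrated 2-D fluorescence images (or wants to validate such a
chain):

1. **segment** — fields of view are tiled into 20 × 20 µm blocks; each block
   is thresholded (Otsu with a dynamic-range floor) and 8-connected
   components become labelled fragments.
2. **shape** — per fragment: circularity `4πA/P²` (corner-corrected boundary
   estimator, clipped to [0, 1]), aspect ratio (major/minor axis of the
   moments ellipse), and length (maximum caliper, plus a skeleton-geodesic
   mode for curved junctional fragments).
3. **classify** — the four-category shape classifier: aspect-ratio quartiles
   (Q1/Q2/Q3 of a declared reference population) crossed with fixed
   circularity bins — category 1: AR > Q3, circularity 0–0.25 … category 4:
   AR < Q1, circularity 0.75–1. Percentages are reported per field of view
   on the total fragment count.
4. **junction** — zippering metrics per cell: coverage
   `100 × Σ fragment length / perimeter`, fragments per 100 µm of vessel,
   and the cumulative frequency distribution of fragment lengths.
5. **clearance** — one-phase exponential tracer kinetics: enhancement =
   raw − baseline, normalized to the first post-injection timepoint, fit to
   `I(t) = e^(−kt)`; half-life `ln(2)/k`.
6. **stats** — Welch t test and Wilcoxon rank-sum with exact enumeration for
   combined n ≤ 20 (the regime of per-animal comparisons).
7. **synthdata** — a ground-truth scene generator (Voronoi/Lloyd cell
   mosaics, bar and punctum fragments, blur + Gaussian noise; clearance
   series at imaging timepoints 1, 2, 3, 4, 6, 24 h) so the whole pipeline
   is testable without microscope data.

## Worked example

```r
library(junctmorph)

cfg <- run_config(
  out_dir   = "demo_run",
  scene     = scene_spec(seed = 1),           # 100 x 100 um, 9 cells,
                                              # 60 bars + 30 puncta
  clearance = generate_clearance_series(k_true = 0.5, I0 = 1,
                                        baseline = 0.1, noise_sd = 0.02,
                                        seed = 2),
  seed = 1)
res <- run_pipeline(cfg)

res$fov[c("pct_cat1", "pct_cat2", "pct_cat3", "pct_cat4")]
#   pct_cat1 pct_cat2 pct_cat3 pct_cat4
# 1       12       38       11       39
mean(res$junction$coverage_pct)
# [1] 13.40503
res$clearance_fit
# <clearance_fit> k = 0.4715 /h, half-life = 1.470 h (rss 0.00631)
```

Reading: 39% of fragments fall in category 4 (round, low aspect ratio —
puncta from VE-cadherin turnover) and 50% in categories 1–2 (elongated
junctional bars), matching the generated 30:60 mix once block-boundary
splitting is accounted for; junctional VE-cadherin covers ~13% of the cell
perimeters (a sparse button-like scene); and the fitted clearance constant
0.47 h⁻¹ recovers the generating k = 0.5 h⁻¹ within the noise.

All inter-stage tables are written as CSV to `out_dir` together with a
`manifest.json` recording the seed and configuration, so any stage can be
re-run or replaced.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the main end-to-end computation (simulate → segment → shape →
classify → junction metrics → clearance fit) under the given seed, prints a
short summary, and writes the results JSON.

## Scope

Wet-lab procedures, vessel-density tools, flow cytometry, and any automatic
cell-outline segmentation are out of scope; cell perimeters come from ground
truth (synthetic scenes) or annotation files. See the methods vignette
(`vignettes/junction-morphometry.Rmd`) for the model, parameter choices, and
known limitations.
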