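---
title: "bluefield: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bluefield: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bluefield)
```

## The problem and the pipeline

Object detectors for field agriculture need images of plants in soil
with accurate bounding boxes. Indoor imaging rigs photograph plants
against blue keying fabric, which makes segmentation trivial and labels
free — but indoor images differ from field images in background,
lighting, and plant color. `bluefield` closes that gap with a
deterministic, seedable pipeline:

1. **Chroma-key segmentation.** A pixel is backdrop when its blue
   channel dominates: `B − max(R, G) ≥ t`. The plant mask is the
   complement; the label box is the mask's tight extent.
2. **Composite formation.** The cutout is rescaled so its longest side
   is a fraction `s ~ U(S_min, S_max)` of a square tile (defaults
   0.50–0.85 of 256 px), placed at a uniformly random offset, and
   painted over a randomly cropped soil window: plant pixels where the
   mask is true, soil elsewhere.
3. **Plant color correction.** In 8-bit CIELAB, each masked pixel is
   shifted per channel by (target − masked mean), clamping to
   [0, 255]; unmasked pixels are untouched. Default targets
   (170, 100, 160) lighten and yellow the plant toward field
   appearance. Mean matching is used rather than histogram matching: the
   translator is still expected to adjust plant color, so only the
   first moment needs to be right.
4. **Translation.** Any function from a square RGB tile to a same-size
   RGB tile. The identity and a channel-statistics transfer are built
   in; a trained generator plugs in through an external-command adapter.
   The training objective of one-sided contrastive translation (the
   adversarial loss plus temperature-scaled patch contrastive losses on
   both domains) is implemented as pure, testable math; gradient-based
   training is deliberately behind the adapter boundary, since it is
   GPU-scale and contributes nothing checkable at desk scale.
5. **Background correction.** Translation may drift the tile's soil
   statistics away from the surrounding field image. The per-channel
   mean difference between composite and translated tile over the
   plant-bbox exterior is added back uniformly, clamped to [0, 255].
6. **Scene assembly.** Each plant's corrected tile replaces its
   rectangular soil window (no feathering — faithful to plain
   sub-section replacement). Labels are the per-plant mask extents
   offset into scene coordinates, so they are exact by construction.

## Coordinates and conventions

One convention is used everywhere: row-major pixel grids, origin
top-left, 0-based, half-open boxes `[x0, x1) × [y0, y1)` with area
`(x1−x0)(y1−y0)`. Exporters convert at the boundary: YOLO normalizes
centers/sizes to [0,1] at fixed 6 decimals, Pascal VOC XML uses 1-based
inclusive corners, CSV keeps the native convention.

The 8-bit CIELAB encoding (`CIELAB8`) scales L from [0,100] to [0,255]
and offsets a and b by +128 — the common byte-image convention, and the
only one under which the default plant targets (170, 100, 160) are
meaningful. Under it, green has a < 128 and yellow b > 128. Conversion
assumes sRGB with the D65 white point.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| chroma threshold `t` | 30 | intensity levels | backdrop when `B − max(R,G) ≥ t`; configurable since real fabric tone varies |
| min component area | 0 (off) | px | speckle removal after thresholding; fixtures are noise-free so it defaults off |
| tile side | 256 | px | generator input size |
| `S_min`, `S_max` | 0.50, 0.85 | fraction of tile side | plant scale range |
| color targets (L, a, b) | 170, 100, 160 | CIELAB8 levels | field-plant channel means |
| PatchNCE temperature τ | 0.07 | — | softmax scale of the contrastive unit |
| loss weights λ_X, λ_Y | 1, 1 | — | default objective weighting |
| split proportions | 0.8/0.1/0.1 | — | val/test sizes rounded, remainder to train |
| bbox margin | 0 | px | tight boxes; no geometric pre-crop (needs rig metadata) |
| placement attempts | 100 | — | rejection-sampling budget per plant |

## Numerical choices

- **Rounding.** All pixel arithmetic runs in doubles; outputs are
  rounded half-even (base R `round`) then clamped to [0, 255]. Because
  stored pixels are integers and correction offsets are constants, a
  corrected region's mean lands within 0.5 of its target absent
  clamping — the property the test suite asserts for both corrections.
- **Resampling.** Bilinear for images (soft edges), nearest-neighbor
  for masks (stays boolean). Output length of the longest side is
  `round(s × tile side)`; the short side is rounded from the aspect
  ratio, preserving it within one pixel.
- **Color round trip.** Quantizing a and b to integer levels moves
  saturated RGB values on re-conversion; on composite imagery the
  round-trip error is bounded in tests at ≤ 4 levels worst case, ≤ 2 at
  the 99th percentile, mean < 0.5. Scene assembly avoids paying this
  cost on background pixels by restricting the CIELAB round trip to
  masked (plant) pixels.
- **Stabilized losses.** The contrastive unit is evaluated via
  log-sum-exp, finite for any finite features; probabilities in the
  adversarial loss are clipped at 1e-7. The naive textbook form of the
  contrastive unit loses all precision when the loss is near zero
  (`log(1−ε)`), so oracle comparisons in the tests are restricted to
  well-conditioned cases (naive value ≥ 1e-6).
- **Matching policy.** Detection matching is greedy in descending
  confidence, each prediction taking the unmatched ground truth of
  highest IoU at `IoU ≥ threshold` (VOC style; ties on ≥ differ from >
  only on measure-zero cases and match common tooling). Reported
  precision/recall use all predictions at IoU 0.5 — the operating point
  is a package choice, documented because detector validators differ.
- **Degenerate inputs.** Empty masks, all-false regions, zero
  temperatures, oversized cutouts, undersized backgrounds and exhausted
  placement budgets all raise typed errors naming the violated
  precondition; AP with no ground truths and no predictions is defined
  as 0 with a warning.

## Randomness and reproducibility

Every stochastic operation takes a seed; a counter-based
multiplicative-congruential fan-out (`derive_seed`) gives each scene,
plant, and stage an independent stream, so adding a plant never
perturbs earlier plants, and the first *k* plants of a scene are
invariant under growing `n_plants`. A dataset build records its config,
master seed and pool parameters in `manifest.json`; rebuilding from the
manifest reproduces every PNG and label file byte-identically, which
the acceptance checks verify by digest.

## What the fixtures emulate — and what they do not

The fixture generator paints rosettes of rotated ellipses on uniform
reference blue (40, 60, 200), recording exactly the painted pixels, and
builds soil as low-frequency correlated noise around a base brown with
speckle, guarded so no soil pixel is ever blue-dominant. This
reproduces the properties the pipeline relies on — chroma separability,
green plant statistics near CIELAB8 (120, 110, 150), size variability —
with a known ground truth, so mask recovery can be asserted exactly at
noise 0. The leaf semi-major axis is fixed at 0.24 of the frame so the
rosette never clips the border and a single leaf's pixel count follows
the analytic ellipse area. Fixture soils default to 1024×1024, a
scaled-down stand-in for full-resolution field frames that comfortably
hosts 3–4 non-overlapping 256 px tiles under rejection sampling.

Fixtures are *not* photorealistic: no leaf veins, shadows, perspective,
lighting variation, occlusion, or species-discriminative morphology.
Passing tests therefore demonstrate the pipeline's arithmetic,
bookkeeping and determinism on chroma-separable input — not that a
detector trained on its output transfers to real fields, which requires
real imagery and a trained translator.

## Problem sizes used in the checks

The shipped test suite and acceptance script run entirely on generated
data: pools of 4–6 cutouts and 1–2 soils; 50–100 composites per
correction suite; 1,000 random patch sets for the loss oracle; 100
random detection scenarios (≤ 30 boxes) against brute-force
re-implementations; 10–20 identity-translated scenes for label
fidelity; and 5-scene datasets for byte-identity rebuilds. These sizes
were chosen to exercise every code path at tight tolerances while
keeping a full run in the order of a minute.

## Known limitations

- No blending or feathering at the tile boundary; the rectangular seam
  is visible with translators that alter soil texture (background
  offset correction reduces, not removes, it).
- Non-overlap is enforced on tile boxes, which is stronger than
  plant-pixel overlap; dense plantings need a larger canvas or smaller
  tiles.
- Multi-plant instance separation is limited to connected components;
  touching plants segment as one.
- The external translator adapter validates shape and range but cannot
  validate semantic quality of a plugged-in generator.
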