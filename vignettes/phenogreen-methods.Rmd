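---
title: "Methods: segmentation, morphometry and the greenness index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, morphometry and the greenness index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phenogreen quantifies growth and verdancy of plants cultured in vitro from
side-view RGB photographs taken through the vessel wall, against a blue
background chosen to make colour thresholding easy. This vignette explains
the model behind each stage, the tunable parameters and their defaults, what
the synthetic scene generator does and does not emulate, and the numerical
conventions that make results reproducible bit for bit.

## The segmentation model

A vessel photograph contains three colour populations: plant tissue
(green through chlorotic yellow-green), the deep blue background, and an
optional pale band of culture medium at the vessel base. Two channels
separate them:

* **CMYK yellow (Y) channel.** With $R' = R/255$ etc.,
  $K = 1 - \max(R', G', B')$ and $Y = (1 - B' - K)/(1 - K)$. Any pixel
  whose blue component is the channel maximum has $Y = 0$, so background
  and bluish medium score 0 while leaf pixels score high. Foreground is
  kept where $Y > 45$ (8-bit scale). There is no single CMYK standard;
  the package adopts the ubiquitous max-based ("naive") decomposition
  with the convention $C = M = Y = 0$ where $K = 1$.
* **CIELAB a\* channel.** The green-red axis, computed under D65/2°,
  encoded 8-bit as $a_8 = a^* + 128$. Foreground is kept where
  $a_8 \le 124$ (signed $a^* \le -4$, the green side). Keeping
  at-or-below in one step is exactly the classic "threshold above, then
  invert" sequence. This branch recovers tissue dulled or partially
  obscured by the medium, which the Y branch can miss.

Each branch is cleaned independently, following the published step order:
the Y mask gets a 5×5 square closing (dilation then erosion with the same
kernel — the erosion kernel size is not stated in the source protocol;
the conventional closing reading is adopted) followed by an opening with
the 3×3 cruciform element, which deletes isolated pixels and 1-px spurs.
The a\* mask instead has 8-connected components smaller than 50 px
removed (the protocol's "fill" step has no stated size; 50 px is the
configurable default). The two masks are fused by pixelwise logical OR,
and the mask zeroes the background of the cropped image.

The description of an "area opening" performed *with a 3×3 cruciform
kernel* is ambiguous — a true area opening takes an area parameter, not
a kernel. The kernel reading (morphological opening with the cross) is
implemented; the area reading is effectively available through
`fill_small()`.

Images are cropped before any analysis; the default 2800×2600 window,
centred by default (the anchor is configurable since the original anchor
is unstated), matches the published workflow on 6000×4000 photographs.

Border convention: outside the canvas counts as background for both
dilation and erosion (as in `scipy.ndimage` with `border_value = 0`), so
closing is extensive only away from the image border. Plants sit well
inside the crop, so this never matters in practice, but property tests
respect it.

Automatic threshold selection (e.g. Otsu) is deliberately out of scope:
the fixed thresholds 45 and 124 are part of the method, and the original
study found automatic selection unhelpful for this imaging setup.

## Shape traits

All retained foreground is treated as one composite plant (single plant
per vessel): one convex hull over every foreground pixel, perimeter
summed over components.

* **Area** — foreground pixel count.
* **Convex hull area** — the number of pixel *centres* inside or on the
  convex hull polygon of all foreground pixel centres. Using pixel
  counts for both area and hull area (rather than polygon shoelace
  areas) guarantees solidity $= \mathrm{area}/\mathrm{hull}$ lies in
  $(0, 1]$, with equality exactly for filled convex shapes; polygon
  conventions can push small shapes above 1.
* **Perimeter** — the arc length of each component's external boundary
  walked through 8-connected boundary pixel centres (Moore-neighbour
  tracing): axial steps count 1, diagonal steps $\sqrt 2$; a single
  pixel contributes 0; 1-px-wide structures are traversed out and back.
  The crack-length alternative was rejected so that a 1×n bar measures
  $2(n-1)$, matching the contour convention of the common computer
  vision toolkits.
* **Above/below-medium split** — foreground strictly above the
  configured `medium_row` (1-based index of the first medium row) versus
  the rest; the two counts always sum to the area. Medium detection is
  manual by design: the row is supplied per run (or per image via a
  manifest), as no automatic detection was described for the original
  workflow.

Connectivity is 8-connected everywhere. Exact numeric parity with any
specific legacy toolkit is not claimed — conventions differ between
tools — but every convention used here is stated and tested against
independent oracles (shoelace-invariance point-in-hull for the hull; a
clean-room boundary tracer plus hand-derived values for the perimeter).

## The greenness index

For every foreground pixel the signed CIELAB triple is extracted
(D65/2°, standard sRGB decoding). A pixel *qualifies* if strictly
$a^* < 0$ (green side) **and** $b^* > 0$ (yellow side); neutral pixels
never qualify, and non-qualifying foreground pixels are excluded from
the means entirely rather than zero-filled. With
$\bar a = |\mathrm{mean}(a^*)|$ and $\bar b = \mathrm{mean}(b^*)$ over
qualifying pixels,

$$\theta = \arctan\!\left(\frac{\bar a}{\bar b}\right)\cdot\frac{180}{\pi},
\qquad \mathrm{index} = \theta \cdot \frac{100}{90}.$$

"Absolute of the mean" is read as $|\mathrm{mean}(a^*)|$, which equals
$\mathrm{mean}(|a^*|)$ because qualification makes every $a^*$ negative.
Both means are strictly positive, so $\theta \in (0°, 90°)$, plain
`atan` suffices (no quadrant logic), and the index is strictly inside
$(0, 100)$ whenever defined. The rescaling is linear with fixed
endpoints (0° → 0, 90° → 100); no other form was stated. A verdant
plant (strong green, moderate yellow) scores near 50; progressing
chlorosis shrinks $|\bar a|$ and grows $\bar b$, driving the index
towards 0. Lightness never enters the index.

The qualification filter operates in *signed* Lab units because the
conditions are written with signs ($a < 0$, $b > 0$); the 8-bit offset
encoding (where the same conditions would read $a_8 < 128$, $b_8 > 128$)
is used only for the segmentation threshold 124. When no pixel
qualifies (e.g. an empty mask, or a fully non-green plant) the index is
undefined: the package signals a typed condition and batch processing
records a missing value rather than aborting.

Greenness is a colour proxy, not a chlorophyll assay: anthocyanins or
carotenoids would bias it, and no calibration against pigment content is
attempted.

## Colour-space conventions

The white point (D65, 2° observer) and the offset-128 8-bit Lab encoding
are recorded assumptions — the original toolkit version did not state
them — chosen to match the dominant imaging defaults so that the
published threshold 124 is meaningful. All 8-bit outputs round half away
from zero (`floor(x + 0.5)` on non-negative values); base R's
round-half-even would differ on exact halves and break bit-exact tests.
Conversions are validated against `grDevices::convertColor` on a 9×9×9
RGB lattice to within 0.5 per channel.

## The synthetic scene generator

No photographs from the original study were deposited, so the package
ships a generator that emulates exactly the properties the pipeline
relies on: grass-like tillers (curved, tapered strokes from a basal
point) in a green-to-chlorotic colour gradient on a deep blue background
with an optional pale medium band, plus *exact* ground truth (the truth
mask marks precisely the painted pixels; truth Lab values and traits are
recomputed from the rendered image).

Defaults, and why:

* **Canvas 840×960, tiller length 180–400 px, base width 16 px tapering
  towards the tip.** Roughly a 1:3 reduction of the real 2600×2800
  analysis window. The morphological kernels are *fixed* sizes (5×5,
  3×3), so scale changes the method's behaviour: strokes must stay wide
  relative to the kernel, as real tillers are at full resolution. This
  geometry keeps truth solidity in ≈0.17–0.39 across tiller counts —
  the same range the original study reported (0.177–0.381) — which is
  the realism anchor for the default scale.
* **Palette** — background (40, 70, 160), medium (205, 200, 225), leaf
  endpoints (55, 140, 45) → (175, 195, 40). Chosen so the separation is
  *provable*: every interpolated leaf colour with per-channel jitter up
  to ±10 keeps Y > 45 (measured minimum 147), while background and
  medium have Y = 0 and 8-bit a\* of 150 and 134 (> 124). The chlorotic
  endpoint keeps $a^* < 0$ so the greenness index stays defined across
  the whole gradient, falling from ≈52 (chlorosis 0) to ≈22
  (chlorosis 1).
* **Jitter** — uniform integer noise, default ±6, bounded at ±10 where
  the guarantee above is asserted. Uniform (not Gaussian) so the bound
  is exact.
* **Chlorosis $c \in [0,1]$** — linear RGB interpolation between the
  leaf endpoints; $\theta$ decreases strictly monotonically along it.
* **Seeds** — a scene is a pure function of its spec; experiment rows
  use `base seed + row index` so any single scene regenerates
  independently. The global RNG state is saved and restored.

The default 18-scene experiment (6 treatments × 3 imaging days) mirrors
the structure of a hormone trial: chlorosis grows with day and with
cytokinin-like treatments, tiller count is highest in TDZ-containing
treatments (driving solidity up), and size grows with day.

What the generator does **not** emulate: condensation and reflections on
the vessel wall, shading and specularities on leaves, JPEG artefacts,
vessel geometry, overlapping neighbour plants. A green test here
establishes that the pipeline's logic is correct on images satisfying
the blue-background contrast assumption — not that it is robust to the
optical artefacts that make real in-vitro imaging hard.

## Numerical and degenerate-input choices

* Thresholds are strict (`>`) on the Y branch and inclusive (`<=`) on
  the a\* branch — the polarity that reproduces "threshold then invert".
* Empty final segmentation masks produce a warning plus a zero-area
  record with missing shape traits, never an error; unreadable files in
  a batch are logged and skipped.
* Summary tables use mean, standard error $s/\sqrt n$ (0 by convention
  for $n = 1$) and the normal-approximation 95% half-width
  $1.96\,\mathrm{SE}$; a t-based interval was rejected as unstated.
* The mixed-effects modelling of the original study is intentionally out
  of scope; the traits CSV is shaped so that
  `response ~ date + treatment + date:treatment + (1 | plant_id)` can be
  fitted directly in any statistics environment.

## Known limitations

Per-scene segmentation error is dominated by the 5×5 closing bridging
1–4 px gaps between nearby tillers (all error is false positives; raw
threshold recovery is pixel-perfect on the synthetic palette). At the
default scale this keeps mean IoU ≈ 0.97 and per-scene area error below
5%, but scenes rendered much smaller than the default canvas will see
the fixed kernels dominate. Perimeter is convention-sensitive and highly
variable on thin structures, as the original study also observed.
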