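---
title: "Methods: automated comet-assay image analysis with CometKit"
author: "CometKit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated comet-assay image analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

The comet assay (single-cell gel electrophoresis) quantifies DNA damage in
individual cells: fragmented DNA migrates out of the nucleus during
electrophoresis and forms a fluorescent "comet" whose bright, compact
*head* is the residual nucleus and whose *tail* is the smear of migrated
fragments extending in the field direction. High-throughput protocols
produce micrographs with tens of comets at arbitrary positions, often
touching one another and surrounded by debris, and manual outlining is
the rate-limiting step. CometKit automates the full chain: detect every
comet, separate overlaps, measure each comet's damage parameters, and
classify its morphological state.

## The comet model

All head/tail geometry is defined on the one-dimensional *integrated
intensity profile*: for a comet with pixel set $C$, the profile value at
column $x$ is the sum of the comet's own pixel intensities in that
column. Treating intensity as mass:

* **CPH** (center position of head): the column of the profile peak
  (leftmost on ties).
* **HT** (head threshold): a user-set fraction of the peak profile value.
  The head's right boundary is the first column right of the CPH whose
  profile value falls below $HT \times$ peak; its distance from the CPH
  is the head radius $r$.
* The **tail** runs from the right end of the head ($CPH + r$) to the
  last column with positive intensity; the span is the **tail length**.
* $\mathrm{DNA} = \sum_{x \in C} I(x)$ and
  $\mathrm{TDNA} = \frac{1}{\mathrm{DNA}} \sum_{x \in tail} I(x)$,
  the fraction of fluorescence in the tail.
* **CMT** (center of mass of tail): the intensity-weighted mean tail
  column; **tail distance** $= CMT - CPH$.
* The three damage moments:
  $\text{extent} = \mathrm{TDNA} \times \text{tail length}$,
  $\text{Olive} = \mathrm{TDNA} \times \text{tail distance}$, and
  $\text{inertia} = \frac{1}{\mathrm{DNA}}\sum_{x \in tail} I(x)\,(CPH - x)^2$.

TDNA enters the moments as a fraction and lengths in pixels, so a comet
with TDNA 74.84% and a 35 px tail has extent moment 26.19.

### Why HT defaults to 0.5

The head threshold is deliberately user-facing; the package must still
pick a default. We use the half-maximum boundary (HT = 0.5), the classic
"full width at half maximum" head definition, for a quantitative reason:
the head/tail split is only monotone in damage when the tail's per-column
brightness stays below $HT \times$ peak. With a small HT (say 0.1), any
tail brighter than 10% of the head column is absorbed into the "head",
so heavily damaged comets — whose tails are bright — would report *less*
tail DNA than moderately damaged ones. With HT = 0.5 the tail can carry
up to half the head's column brightness and the measured TDNA increases
monotonically with true damage across the whole range. The cost is a
baseline: for an undamaged Gaussian head, the head-fringe columns right
of $CPH + r$ (about 12% of the head mass at half-max) count as tail.
This baseline is a property of every threshold-based head definition; it
is present identically in the ground truth the generator reports, so
recovery comparisons are unaffected.

# The four-stage pipeline

`runPipeline()` executes the stages in fixed order; a
configuration object (`cometConfig()`) plus a seed fully determines the
output.

## Stage 1 — smoothing

Median (default) or moving-average filtering with an odd window
(default 5 px, replicate-padded borders). Median preserves comet edges
while removing shot noise; 5 px is small relative to the smallest heads
we expect (sigma of about 4 px) and large enough to stabilize the
histogram for thresholding. Fractional intensities are kept — no
re-quantization.

## Stage 2 — first-valley binarization and labeling

Comet-assay gray-level histograms always have their first (and by far
largest) peak at the background intensity; comet pixels form a long,
faint continuum above it. Otsu's threshold, which maximizes
between-class variance, lands far into that continuum and misses faint
comets (typically apoptotic cells — exactly the ones an assay must not
lose). We instead take the *first valley*: after moving-average
smoothing of the counts (window 5), the first strict local minimum after
the first local maximum, leftmost on plateaus. Foreground is strictly
above the threshold. When no valley exists (blank or degenerate images)
the pipeline falls back to Otsu, and a fully constant image yields an
empty result rather than an error.

Operationally the valley search runs on run-length-compressed counts,
which makes the plateau tie-break exact. Candidates are then labeled by
8-connectivity; labels are assigned in raster order of each component's
first pixel, so labeling is deterministic.

## Stage 3 — filtering and overlap correction

1. **Border removal**: components touching the image edge are truncated
   comets and are discarded.
2. **Fragment merging**: components below 0.1% of the image pixels are
   debris or detached DNA fragments. They are not deleted — they are
   relabeled to the nearest large component (minimum pixel-to-pixel
   Euclidean distance; ties prefer the larger component, then the lower
   label), because such fragments are part of the nearest comet's
   morphology. With no large component at all they are dropped.
3. **Overlap correction**, per component:
   * *Distance transform*: each foreground pixel receives its Euclidean
     distance to the nearest background pixel (image border counts as
     background at distance 1). This turns the mask into a topographic
     relief whose ridges follow the comet bodies.
   * *Haar wavelet smoothing* (level 2 by default): a 2-D discrete Haar
     decomposition with all details up to the level zeroed; level 1 is
     exactly non-overlapping 2x2 block averaging. This flattens shallow
     pits and bumps narrower than $2^{level}$ px that would otherwise
     over-segment the watershed.
   * *Watershed*: basins are flooded from the regional maxima of the
     smoothed relief, level by level in decreasing height; within a
     level, unassigned pixels repeatedly adopt the smallest neighboring
     basin label using a snapshot of the previous sweep, until stable.
     This makes the partition order-independent and bit-reproducible,
     with watershed-line pixels joining the lowest-index seed. Regional
     maxima use a 0.5 plateau tolerance: the distance transform is
     quantized, and ragged mask boundaries otherwise produce half-pixel
     ridge ripples that seed spurious basins.
   * *Shallow-saddle merging*: adjacent basins whose separating ridge
     rises to within 2 distance units of the lower peak are quantization
     artifacts of one body, not a genuine two-cell waist, and are
     merged. Genuine comet-comet junctions in our scenes have saddle
     depths of 3 or more.
   * *Horizontal merging*: watershed lines across one irregular comet
     run mostly horizontally, producing chunks stacked in y over the
     same x-span. Two 8-adjacent chunks merge when their column ranges
     overlap by at least half of the smaller chunk's span *and* their
     row ranges overlap by at most half — truly side-by-side chunks
     (genuine neighbors split by a slanted watershed line) share rows
     and are left apart. The pairwise relation is closed transitively.
   * *Validity*: each chunk's outer contour (Moore tracing, resampled to
     64 points by arc length) is Fourier-transformed as $col + i\,row$.
     Cells are elliptical, so the lowest frequencies dominate: a chunk
     is valid when the amplitudes of the two lowest frequency magnitudes
     (the $\pm 1$ and $\pm 2$ coefficient pairs, DC excluded) hold at
     least 70% of the total non-DC amplitude, and its area is at least
     3% of the parent mask. We include the $\pm 2$ pair because a real
     comet is not a pure ellipse — the tail taper is a second-harmonic
     feature — and restricting the numerator to $\pm 1$ discards
     genuine tadpole-shaped comets at the published 70% level. Invalid
     chunks are merged into their largest valid neighbor (preserving
     DNA totals), or dropped when isolated. Disconnected islands inside
     one label (which only arise from fragment merging) are kept with
     the main body rather than re-segmented.

Per-component failures (e.g. a mask smaller than the wavelet support)
leave that component unsplit with a warning; the image is never aborted.

## Stage 4 — characterization and classification

Measurements run on the smoothed image after subtracting the estimated
background level (the median intensity of non-comet pixels). Without
this, masked DNA sums include the camera offset and TDNA becomes a
function of mask geometry rather than signal. Each comet yields one
record: bounding box, intensity-weighted centroid, CPH, head radius,
tail length/distance, DNA, TDNA, the three moments, box ratio
(bbox width / height) and area. Degenerate comets are flagged, never
silently dropped; a negative tail distance (CMT left of CPH) is kept
and flagged. `tailDirection = "-x"` mirrors the profile for reversed
acquisitions and returns identical scalar records.

Classification uses histogram-of-oriented-gradients features: the
masked crop is resized bilinearly to 50x50 (and its left half 25x50,
because an apoptotic nucleus sits in the left-half area), gradients are
binned into 9 unsigned orientations over 8x8-px cells, and 2x2-cell
blocks at 1-cell stride are L2-normalized. This is the unique standard
geometry giving exactly 900 features on 50x50 and 360 on 25x50; the box
ratio appended gives 901/361, and separates horizontally elongated
necrotic comets. Four classifiers are provided: three one-vs-one linear
SVMs cascaded in listing order (the first comparison's winner meets the
remaining class), a single softmax layer, SAMME AdaBoost with 200
depth-limited trees, and a CART tree with maximum depth 10. Because no
labeled reference comets ship with the package, training data comes
from the synthetic generator; accuracies on synthetic classes
demonstrate the feature pipeline, not field performance.

# The synthetic-scene generator

`composeScene()` renders seeded scenes with full ground truth, standing
in for real micrographs that are not distributable. A comet is a
Gaussian head (sigma 3.5-7 px, peak 65-230 depending on class) plus a
rightward tail carrying the damage fraction $d$ of total mass: a
brightness ramp tapering into an exponential roll-off, with Gaussian
cross-section. Three archetypes mirror the morphological classes:
*normal* (bright compact head, $d \le 0.08$, short tail), *necrosis*
(bright head, long bright tail, $d$ 0.45-0.62), *apoptosis* (dim head —
peak at most 0.4 of the necrosis default — diffuse cloud, 1.3x wider
cross-section). Two modeling rules keep the render compatible with the
profile measurement model:

* the tail's per-column brightness is capped at 0.4 of the head's peak
  column, keeping the profile unimodal with its peak at the head; when
  the requested mass does not fit under the cap the tail *lengthens*
  instead of brightening — which is also the physical dose response;
* the head is rendered at its archetype brightness and damage moves
  mass into the tail; head dimming across damage states is encoded by
  the class archetypes (the apoptosis head cap), not by scaling every
  comet toward invisibility at high damage.

Rendered intensity below a visibility floor of 6 gray levels (about the
background level of 8) is clipped to zero, so the ground-truth support
only contains signal that is in principle distinguishable from
background in 8-bit data. Scenes add a constant background (8), Gaussian
read noise (sd 2), signal-dependent shot noise
(sd $0.3\sqrt{I}$), and small debris speckles far below the 0.1%
fragment threshold. Forced overlap pairs are placed chained along the
electrophoresis direction with 2-5 px of support overlap, the geometry
in which real comets collide.

Ground-truth records are computed by applying the same profile
measurements to the noiseless render with its exact support mask.
Pipeline-versus-truth comparisons therefore isolate exactly the effects
of noise, thresholding and segmentation — not differences in the
measurement definition.

**What the generator does not emulate**: optical point-spread blur,
uneven illumination and vignetting, gel texture, saturated pixels,
halo artifacts around bright heads, and comets whose tails curve or
overlap their own head. Passing the synthetic suites shows the
algorithmic chain is correct under the stated model; it does not certify
accuracy on any particular microscope's images, for which the
user-facing parameters (HT, smoothing window, histogram smoothing)
exist.

# Evaluation tools

* **Region-based metrics**: pixel-wise precision/recall of a
  binarization against a truth mask.
* **Centroid-based metrics**: a predicted comet is a true positive when
  its centroid lies within 15 px of an unmatched truth centroid.
  Matching is a maximum bipartite matching on the within-radius graph
  (cardinality first, closer pairs as tie-break), so no valid pairing is
  missed even when comets crowd within one radius; undefined
  precision/recall (zero denominators) is reported as 0 with an
  explicit flag so batch averages stay computable.
* **Heterogeneity summary**: mean, sd, quartiles and a histogram of
  per-comet TDNA within an image — genotoxicity reads the spread of the
  response, not only its mean.
* **Equivalent confidence**: discarding comets (e.g. border removal)
  widens confidence intervals; `equivalentConfidence(nFull, nSub,
  conf)` returns the level whose interval at the reduced count has the
  original width, under normal quantiles by default
  ($2\Phi(z_{conf}\sqrt{n_{sub}/n_{full}}) - 1$), with a Student-t
  variant for small samples.

# Numerical conventions

* Matrices are indexed `[row, col]`, 1-based; bounding boxes are closed
  integer ranges; "x" in all formulas is the column index; tails extend
  toward increasing columns by default.
* Histogram bins are uniform over $[0, 256)$, so with 256 bins the left
  edge of bin $b$ is the integer gray level $b - 1$; thresholds are
  reported as the left edge of the last background bin and foreground
  is strictly greater.
* All tie-breaks are deterministic and documented: leftmost profile
  peak, leftmost histogram plateau, smallest Otsu split, raster-order
  labeling, lowest-seed watershed lines.
* The distance transform is the standard Euclidean distance to the
  nearest background pixel (exact, via EBImage's fast transform plus a
  one-pixel background pad at the image border).
* Degenerate inputs are signaled with typed conditions
  (`cometNoValley`, `cometDegenerate`) so callers can fall back
  deliberately rather than crash.

# Problem sizes used in the checks

The packaged verification suites use 416x608 px scenes with 15-25
comets, 20% forced overlap pairs and 8 debris speckles; 200
single-comet scenes spanning damage 0-0.9 for parameter recovery; and
60 comets per class for classifier demonstrations. These sizes give
stable statistics while keeping the whole suite fast on a single CPU.

# Known limitations

* The head model is one-dimensional in x; vertically smeared or curved
  comets are measured along their x-profile only.
* Two comets stacked exactly vertically with the same x-span are
  indistinguishable from one over-segmented comet under the horizontal
  merge rule and will not be separated.
* Very faint apoptotic tails below the binarization threshold are
  invisible to any thresholding method; their TDNA is underestimated
  even though the comet itself is detected.
* The classifiers are trained on synthetic archetypes; applying them to
  real micrographs requires retraining on labeled crops via
  `fitClassifier()`.
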