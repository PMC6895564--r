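---
title: "Quantitative myofiber morphometry with fiberquant: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative myofiber morphometry with fiberquant: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

Histological assessment of skeletal muscle rests on a small set of per-fiber
quantities measured on transverse cross-sections: cross-sectional area (CSA)
and minimum Feret diameter as size metrics, the fraction of centrally
nucleated fibers (CNFs) as a regeneration marker, and per-fiber expression of
marker proteins (embryonic myosin heavy chain, NCAM, Evans blue dye uptake,
or the adult MyHC isoforms used for fiber typing) read out as immunofluorescence
intensity. Manual measurement of whole sections is slow and operator-biased;
automated measurement has to solve one dominant image-analysis problem first:
the laminin-stained basement membrane that outlines each fiber is frequently
interrupted by sectioning and staining artifacts, and a single one-pixel gap
merges two fibers into one region under plain thresholding.

fiberquant implements a five-stage pipeline — gap-tolerant segmentation,
machine-learning classification of candidate regions, CNF detection,
per-fiber fluorescence quantification, and unit-scaled export — together with
a synthetic "phantom" generator that renders muscle-like sections with
exhaustive ground truth, so that every stage is verifiable without any tissue
data.

All analysis is performed on unaltered 8-bit images: no brightness, contrast,
or flat-field manipulation happens anywhere in the pipeline, because
fluorescence intensity is one of the measured outputs.

# Gap-tolerant segmentation

## Conventions

Binarization uses the rule *foreground ⇔ intensity ≥ threshold*, so the
stained boundary network is the foreground and candidate-fiber interiors are
the complement. Lowering the threshold thickens the boundary. The choice of
`≥` over `>` is arbitrary at 8-bit quantization and is fixed and documented
here. Interior regions are labeled with 4-connectivity while boundary
reasoning uses 8-connectivity, so that an 8-connected one-pixel boundary
chain separates interiors and thin boundaries cannot leak diagonally.
Region labels are assigned in row-major order of each region's first pixel,
which makes every labeling deterministic.

## The threshold-series tracking algorithm

A `gap_fill_config()` names two thresholds: the *thick* endpoint (thickest
plausible boundary, smallest interiors) and the *thin* endpoint (thinnest
boundary). `fill_gaps()` derives which endpoint is which by counting boundary
pixels rather than trusting the argument order, builds an evenly spaced
series of `n_steps` thresholds between them, and then:

1. Interiors at the thick endpoint become tracked *seed* regions.
2. At each thinner step, every tracked region is located inside the interior
   region that now contains it (interiors only grow, so containment is
   well defined).
3. If the containing region's area exceeds the tracked area by more than
   `expansion_ratio` (default 0.20) *and* the tracked region has at least
   `min_track_area` pixels, the region is deemed to have escaped through a
   stain gap: it is frozen at its prior extent and a *white filler* is
   written into the pixels of the expansion that touch the prior region's
   border (8-connectivity). Filler is permanent boundary for all later steps.
4. If two tracked regions come to share one interior region — a gap between
   two fibers has opened — all of them are frozen and each is sealed by its
   own filler shell. We seal with the full one-step dilation shell rather
   than only the pixels equidistant from the two regions: the shell is a
   superset of the equidistant set, closes the leak channel completely, and
   uses the same geometry as rule 3.
5. Expansion pixels beyond the filler are released and re-tracked as separate
   regions, as are interior regions that appear at later steps without
   containing any seed. The final segmentation is the set of tracked regions
   after the thin-endpoint step.

Two design parameters deserve comment. `min_track_area` (default 50 px)
exists because legitimately small seeds grow by large *relative* amounts as
the boundary thins; without the guard, noise specks would freeze instantly
and litter the segmentation. `n_steps` (default 10) controls how much the
boundary may thin between consecutive steps: gaps are caught when the escape
happens within one step, so more steps make the expansion test more local.
Filler pixels are permanent once written; whether they should be re-evaluated
at later thresholds is not determinable from first principles, and permanence
is the conservative choice (a sealed leak stays sealed).

With intact boundaries the algorithm reduces exactly to plain thresholding at
the thin endpoint — no filler is written and the output equals
`naive_segment()` — which is also how the test suite separates the cost of
the machinery from its benefit.

# Classifying candidate regions

Segmentation yields both myofibers and non-fiber regions (interstitial space,
vessels, artifacts, and gap-filled fragments of them). Four shape descriptors
feed a support vector machine with a radial-basis-function kernel:

* **area** — pixel count;
* **eccentricity** — of the inertia-equivalent ellipse,
  `sqrt(1 - (b/a)^2)`, i.e. focal distance over major axis length. Second
  moments include each pixel's own 1/12 unit-square inertia, which keeps a
  single pixel at eccentricity 0 and a one-pixel-wide line strictly below 1,
  so the `[0, 1)` contract holds for every region;
* **convexity** — area over convex area, where convex area counts the pixels
  whose centers lie inside the convex hull of the region's pixel centers.
  With this definition every convex rasterized shape has convexity exactly 1
  and the value can never exceed 1 (a corner-based hull would add a
  half-pixel annulus and push a radius-30 disc down to ~0.96);
* **circularity** — `4π·area / perimeter²`. The perimeter estimator is the
  convex-contour length: the perimeter of the convex hull of the region's
  pixel corners. Local crack/chain-code estimators carry an
  orientation-dependent bias of 5–13% on discs and squares, which would make
  circularity values estimator artifacts; the convex contour is exact for
  convex shapes — which myofiber profiles approximate — and a lower bound for
  concave regions, inflating their circularity slightly. Since concave
  regions in sections are overwhelmingly non-fiber, this bias is harmless for
  classification; circularity values of strongly concave objects should not
  be interpreted in isolation.

Features are standardized (z-score on training statistics) before kernel
evaluation. The standardization is performed by the package itself rather
than by the SVM backend because the backend silently disables scaling of
*all* features when any single feature is constant, which happens in tiny
training sets. The kernel width default is `gamma = 1/4` (one over the
feature count), which on standardized features matches the common
variance-scaled heuristic; `cost = 1`. Both are exposed. Training is
deterministic under a fixed seed, and training data persist as a
version-stamped plain-text CSV of feature vectors and labels — retrainable
across sessions and package versions, unlike a serialized model object.
A correction step (`apply_corrections()`) flips the call of listed region
ids, mirroring interactive proof-reading; toggling twice is the identity.

# Centrally nucleated fibers

A fiber is called centrally nucleated when at least one nuclear-channel
pixel survives inside the fiber after its area has been eroded by
`erosion_percent` (0–99, default 80). Erosion is *area-targeted*: repeated
one-pixel 4-connected erosions until at most `1 - erosion_percent/100` of the
original area remains, returning the first iterate at or below the target.
Because the amount removed is a percentage of area, the exclusion depth
scales with fiber caliber, so small regenerating fibers are evaluated with
the same setting as large ones — a fixed-radius erosion would either miss
peripheral nuclei on large fibers or annihilate small ones. Fibers whose core
erodes to nothing are flagged `core_empty` and never called positive.

The nuclear channel is binarized at a configurable threshold (default 128;
the phantom renders nuclei ~20 SD above background so the setting is not
delicate on synthetic data, but on tissue it should be set against the
DAPI exposure). Colocalization means at least one overlapping pixel; no
minimum overlap area is imposed. Raising `erosion_percent` can only shrink
the eroded core (iterates are nested), so it can never convert a negative
fiber to positive — a monotonicity the tests assert.

# Fluorescence and fiber typing

Per-fiber mean fluorescence intensity (MFI) is the arithmetic mean of the
marker channel over the fiber's member pixels, computed exactly (the tests
compare against a direct-summation oracle at 1e-12). Positive fibers are
called with a seed-fiber rule: the user designates the dimmest fibers that
are still unambiguously positive, the *minimum* of their MFIs becomes the
channel threshold, and every fiber with MFI at or above it is positive. The
minimum (rather than the mean) of the seed MFIs is used so that every seed is
itself positive and the rule is closed: recomputing with the current positive
set as seeds reproduces the same set.

Fiber typing combines per-channel calls for the type I, IIa and IIb MyHC
channels: single-positive fibers take their channel's type, multi-positive
fibers are hybrids, and all-negative fibers are type IIx in mouse mode (the
standard three-antibody panel leaves IIx unstained) or `unassigned` in
generic mode, for species or panels where exclusion is not valid.

# Size metrics and export

The minimum Feret diameter is the smallest caliper width over all
orientations, computed by rotating calipers on a convex hull. The hull is
taken over a sub-pixel object outline: the 0.5-level marching-squares contour
of the 3×3 box-smoothed mask. For a straight edge of any orientation the
half-coverage crossing of a box filter lies on the edge itself, so the
orientation-dependent staircase bias of raw rasterization largely cancels: an
axis-aligned w-pixel-wide rectangle measures exactly w, and the same
rectangle rasterized at 45° measures within ~0.6 px of w. That residual is a
quantization floor, not an estimator defect — a digital band 10 px wide at
45° is genuinely consistent with continuous widths between 9.9 and 11.3 px —
so rotation invariance should be relied on at calibers of a few tens of
pixels and above, where 0.6 px is within 2%. Regions too small or thin to
carry a half-coverage contour (single pixels, one-pixel lines) fall back to
the hull of their pixel corners, giving the pixel-width convention
(a one-pixel region measures 1).

Physical units use an explicit `microns_per_pixel` scale (named to remove the
px-per-µm ambiguity): `area_um2 = area_px · scale²`,
`min_feret_um = min_feret_px · scale`. Records export to CSV with a fixed
column order and 17-significant-digit numerics, so re-import reproduces every
double exactly; XLSX is deliberately not written (binary format). Two
evaluation statistics are provided: `accuracy(test, manual) =
(1 − |test − manual|/manual) · 100`, symmetric in the error direction and
never above 100, and `cv(x) = sd(x)/mean(x) · 100` with the sample (n−1)
standard deviation.

# The phantom generator

`make_phantom()` renders a synthetic section and its exhaustive ground truth.
The model: fiber cross-sections are Voronoi cells of Poisson-disk (dart
thrown, minimum-distance) seeds — convex, size-regular mosaics resembling
healthy muscle; uniform seeding would produce degenerate slivers. The
boundary network is the band where the distance to the second-nearest seed
exceeds the nearest by at most `boundary_thickness`. A configurable fraction
of cells is interstitial: a thin bent channel is kept dark and the rest of
the cell is filled at boundary intensity, emulating connective tissue with
embedded low-convexity, low-circularity spaces — which is what makes the
classification task non-trivial. Gaps are cut as arcs of *intermediate*
intensity (default mean 150) on the shared boundary of two fiber cells:
closed at the thick threshold, open at the thin one, i.e. weakly stained
boundary stretches rather than absent ones. Nuclei are discs (radius 2 px,
proportionate to the ~5 µm nucleus / ~40 µm fiber ratio at the phantom's
working resolution) placed at the fiber centroid (CNF) or within two pixels
of the boundary (peripheral). Marker channels draw each fiber's pixels from
a normal distribution whose mean depends on the fiber's type; types are
allocated by largest-remainder counts from the configured proportions
(defaults 0.35/0.30/0.25/0.10 for I/IIa/IIb/IIx, a mixed-muscle profile).

Default intensities (mean ± SD on the 8-bit scale): boundary 220 ± 8,
interior 40 ± 8, gap 150 ± 4, nuclei 220 ± 10 over 20 ± 5 background, marker
positive 180 ± 10 vs negative 40 ± 10. These give ≥5 SD separation between
every pair of classes that a threshold has to distinguish, so segmentation
and positivity are exactly recoverable at the recommended thresholds — by
construction, ground truth and rendering are consistent before noise, and the
noise never crosses a decision boundary at these SDs. Noise is additive
Gaussian clipped to [0, 255], with no blur, so oracle thresholds stay
analyzable. `phantom_gapfill_config()` returns the matching segmentation
endpoints: thick midway between interior and gap intensity, thin 5 SD below
the boundary mean.

`dystrophic_preset()` modifies a configuration toward dystrophic morphology:
clusters of small-caliber fibers (raising CSA variance), 30% gapped fibers,
60% CNFs, and more interstitial cells. It returns a new configuration and
leaves its input untouched.

What the phantom does **not** emulate: optical blur and chromatic aberration,
uneven illumination and stitching seams, saturated nuclei clusters and
overlapping nuclei, out-of-plane (oblique) sectioning, autofluorescence, and
fiber-boundary curvature beyond convex polygons. Passing the phantom suite
therefore demonstrates algorithmic correctness under the stated image model —
not robustness to every acquisition artifact; thresholds and training labels
still need to be set per dataset on real tissue.

# Validation scale and reproducibility

The test suite validates: exact fiber recovery and per-fiber areas on a
200-fiber phantom; gap recovery (≥95% of fibers one-to-one at IoU > 0.7,
filler confined to annotated gap corridors) on a 30%-gapped 100-fiber
phantom; shape descriptors against closed forms and an independent
hull-rasterization oracle over 50+ random polygons; ≥95% held-out SVM
accuracy with 25 labels per class on a 200+200-region phantom; exact CNF
calls (no false positives or negatives at default erosion, fibers ≥ 200 px)
and erosion monotonicity; exact MFI, threshold-rule closure on 100 random
MFI vectors, and exact fiber-type recovery; the metric formulas against
two-pass oracles; and byte-identical exports across repeated runs, up to a
2,000-fiber dystrophic section. These sizes were chosen so the whole suite
runs in minutes on a single core while every claim is exercised at a scale
where raster quantization sits inside the stated tolerance.

```{r example}
library(fiberquant)

ph  <- make_phantom(phantom_config(n_fibers = 120, gap_fraction = 0.2,
                                   seed = 1))
cfg <- phantom_gapfill_config(ph)
seg <- fill_gaps(ph$channels$laminin, cfg)
rois <- extract_rois(seg$segmented)
fiber_recovery(seg$segmented, ph)$recovered_fraction
```

# Known limitations

* Fibers touching the image frame are truncated, not excluded; downstream
  size statistics on real sections should filter them.
* The CNF stage detects central nuclei only; peripheral myonuclear counting
  is out of scope (dense or overlapping nuclei cannot be resolved per fiber
  at this level of modeling).
* Circularity of strongly concave regions is inflated by the convex-contour
  perimeter (see above).
* Minimum Feret values below ~20 px carry raster quantization of up to
  ~0.6 px at unfavorable orientations.
* The seed-fiber positivity threshold is a per-channel global minimum; it
  does not model spatially varying background.
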