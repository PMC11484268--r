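---
title: "Quantifying lesion progression: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lesion progression: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionflow)
```

This vignette is the package's own account of its methods: what each score
measures, which choices were genuinely open and how they were resolved, and
what the synthetic test bed does and does not establish about real
dermoscopic data.

## Scope and assumptions

`lesionflow` analyzes *registered* sequences of dermoscopic RGB frames of a
single pigmented lesion: all frames share one canvas and depict the same
lesion without camera motion, as is the case for synthetically interpolated
progressions and well-registered follow-up imagery. One lesion per image is
assumed; every metric first reduces the mask to its largest 8-connected
component. Geometry uses 1-based (row, col) coordinates with pixel centers
at integer positions throughout, so no half-pixel offsets can accumulate
between metrics.

Masks may be supplied per frame (8-bit PNG, 0 background / 255 lesion) or
derived by the baseline segmenter: Otsu's threshold on the luminance image,
keeping the darker side (pigmented lesions are darker than surrounding
skin), cleaned by morphological closing (disk radius 3 px) and hole
filling. This baseline is deterministic and intentionally simple; it is a
stand-in for whatever segmentation pipeline produced the user's masks, and
user masks always take precedence.

## Color normalization

Simulated or re-acquired frames often drift in overall color. The
normalization anchors every frame to the first frame's healthy skin: the
mean RGB over the union of the four corner patches (default `patchSize` 20
px, small enough to stay within healthy skin on a 160–256 px canvas and
required to be at most min(H, W)/4) is converted to CIELAB (D65, via
`grDevices::convertColor`), and the offset `reference − frame corner mean`
is added to *every* pixel of the frame in LAB before converting back with
gamut clipping. Applying the same offset to lesion and skin alike is
deliberate: the correction models global illumination, not lesion change.
The four corners are averaged jointly (not per corner), and the operation
is idempotent up to sRGB↔LAB round-trip error (≤ 1 intensity level), both
verified in the tests.

## The per-frame scores

**Asymmetry.** The mask's moment-equivalent ellipse (center = centroid,
axes = 4·√eigenvalue of the second central moments, so a filled ellipse
recovers its own axes) fixes the lesion's intrinsic frame. The luminance
image is rotated about the ellipse center (bilinear; nearest-neighbor for
the mask) so the major axis is horizontal, cropped to the rotated mask's
bounding box, and split at the ellipse center. Halves mirror about the
line `k + 0.5`, so the split index is the *floor* of the center
coordinate — using the nearest integer instead pairs every row off by one
and destroys exact mirror symmetry. The shorter half is padded with the
background level (median intensity outside the mask, a neutral fill that
does not penalize symmetric lesions with odd-sized boxes). Each mirrored
pair is compared by SSIM on the grayscale crop (uniform 7×7 window, data
range 255, statistics restricted to windows that fit entirely); the score
is the mean of the two `1 − SSIM` values, clamped to [0, 1]. SSIM is
computed on grayscale rather than per channel: structural asymmetry is a
luminance phenomenon, and the color axes are covered by the color scores.
Note that SSIM reads *uncorrelated noise* between halves as dissimilarity;
at noise levels above a few intensity levels a perfectly symmetric lesion
scores measurably above zero.

**Border gradient.** Sobel 3×3 responses on the luminance image (replicate
borders) give a magnitude map that is divided by the largest magnitude the
operator pair can produce at data range 255. That constant is 510·√5
(attained by the support-function maximum over all 0–255 neighborhoods —
not √2·1020, which no image achieves). A fixed normalizer, rather than the
per-image maximum, keeps scores comparable across the frames of a
trajectory; a per-image maximum would silently re-scale every frame and
make trends meaningless. The score is the mean magnitude sampled at the
traced outer contour of the mask (contours shorter than 8 points are
rejected).

**Convexity.** Pixel-count ratio of the lesion to its filled convex hull,
where "filled" means pixel centers inside or on the hull of the lesion
pixel centers (half-plane test with a 1e-9 slack). A filled rectangle
scores exactly 1; collinear-degenerate masks score 1 by convention.

**Diameter.** The infinite line through the ellipse center along the major
axis is intersected with the contour polygon; the score is the distance
between the extreme intersections, converted to millimetres when a
mm/pixel scale is available. If the line misses the contour (pathological
masks), the extreme lesion pixels projected on the axis are used and a
warning is raised. On a rasterized disk of radius r the result is ~2r − 1
(contour pixel centers sit half a pixel inside the ideal circle), which is
why the tests allow ±2 px.

**Color clustering and dispersion.** Lesion colors are analyzed in linear
RGB (inverse sRGB gamma), where Euclidean distances track physical
intensity. Because 8-bit images place colors on a quantization lattice,
intensities are first dequantized with seeded uniform ±0.5-level jitter —
without it, the lattice atoms read as spurious modes and a uniform lesion
with very low noise can be shattered into many clusters. Unimodality is
then tested with Hartigan's dip statistic on the projection of the colors
onto their first principal direction (the dominant color axis; a 3-D
distribution must be reduced to 1-D for the dip, and PC1 is the documented,
swappable choice), evaluated on at most 2000 evenly spaced order statistics
with residual ties spread evenly between neighboring distinct values. The
p-value comes from 500 Monte-Carlo uniform null samples of the same size
under a fixed internal calibration seed (cached per sample size), so
results are deterministic. If p ≥ α (default 0.05) the lesion is one color
mode; otherwise k ∈ 2..6 is selected by the best mean silhouette of
seeded k-means partitions (10 restarts) on a deterministic ≤ 2000-pixel
subsample, and all pixels are labeled by Lloyd refinement from the chosen
centers.

The dip statistic itself is computed by the modal-interval construction —
iteratively comparing the greatest convex minorant and least concave
majorant of the empirical cdf on a shrinking interval, in count units over
distinct values so ties are handled exactly. It reproduces the exact
closed forms (1/(2n) for equally spaced points, 1/4 for two equal point
masses) and is affine- and duplication-invariant. One known conservatism:
a large atom located exactly at the mode inflates the statistic by about
half its relative mass, because the implementation does not credit the
unimodal class's freedom to jump at the mode; for quasi-continuous image
data (dequantized, small multiplicities) the effect is negligible.

Dispersion is the cluster-weighted standard deviation of pixel-to-centroid
distances, normalized by √3/2 (half the unit-cube diagonal — the tightest
constant that maps the most extreme two-point cluster near 1) and clamped
to [0, 1]. This is a *within-cluster* quantity: a lesion split evenly
between pure black and pure white in one cluster has all distances equal
to √3/2 and therefore dispersion zero, and once such a lesion is split
into two clusters each is internally uniform. The popular intuition that
"black and white" should score near 1 is inconsistent with the
within-cluster definition; the definition is kept and the inconsistency
documented rather than resolved. A practical consequence: when distinct,
well-separated color modes emerge over a sequence, the dispersion
trajectory is discontinuous at the frame where the unimodality gate first
rejects (between-mode spread moves from within one cluster to between
clusters). The synthetic preset below is designed so this transition is
continuous.

**Color evolution.** Between two segmentations, the side with fewer
clusters drives a greedy matching by descending mask-IoU (each cluster
used once; ties broken toward lower indices; nearest-centroid fallback
with a warning if no masks overlap). Matched centroid distances are
averaged, normalized by √3, and scaled by m/max(kA, kB) with m the number
of matched pairs — the reading of "normalized by the maximum number of
clusters" under which unmatched clusters neither dilute the average nor
push the score out of range.

## Optical flow

Dense flow between consecutive frames uses quadratic polynomial expansion:
each luminance neighborhood is approximated as
`f(u) ≈ c + bᵀu + uᵀAu` via Gaussian-weighted least squares (applicability
size 5, σ 1.2), computed with separable correlations and a precomputed
6×6 metric inverse. Displacements solve the aggregated normal equations
`(Σ w AᵀA) d = Σ w Aᵀ Δb` over a 15 px box window, iterated 3 times per
level of a 3-level pyramid (scale 0.5), warping the second frame's
expansion by the current field. The parameters are pinned and exposed via
`flowParams()`; determinism requires pinning them. Near-singular solves
(flat regions) return zero, and displacements are clamped to the window
size per iteration — beyond the window the estimator has no pull-in range
and unclamped solutions produce spurious ~100 px vectors. Flow is
undefined where there is no texture: the estimate is invariant to
intensity scaling, so no amount of smoothing rescues a textureless noisy
region. On exact integer translations of a textured lesion the
implementation recovers the displacement to well under 0.1 px (the
acceptance suite requires 0.5 px).

Accumulation sums the per-pair *vectors* (not magnitudes), so opposing
motions cancel — a property, not a bug: the map highlights net change at
the cost of per-step direction, and the tests verify both the recovery of
two stacked translations and the cancellation of a there-and-back pair.
The heatmap min-max scales the magnitude per sequence (no absolute scale
is meaningful across sequences) through a blue→green→red map, optionally
alpha-blended onto the final frame with a 16 px-stride quiver. The
radial-expansion statistic averages, over a ±2 px band around the mask
boundary (5 px disc dilation minus erosion), the dot product of the
accumulated vector with the outward radial direction from the mask
centroid; rigid translations cancel around the boundary by symmetry.

## Sequence statistics

First-vs-last deltas are relative (`100·(last − first)/first`) unless the
baseline is below 1e-6, in which case the absolute difference is reported
and flagged. Correlations against a classifier-confidence series use the
product-moment formula with two-sided t-tests on n − 2 degrees of freedom
(`stats::cor.test`; an independent closed-form oracle re-derives both in
the tests); constant series yield `NA` rather than 0, because an undefined
correlation is not a zero correlation. Raw p-values are reported by
default, matching common practice for small per-sample tables;
Benjamini–Hochberg adjustment is available behind `pAdjust = "BH"`.
Distribution summaries use type-7 (linear interpolation) quantiles —
stated explicitly because boxplot conventions differ between ecosystems.

## The synthetic generator

The generator renders what the analysis assumes: a roughly elliptical
pigmented lesion on lighter skin. The boundary is an ellipse modulated by
a seeded odd-harmonic radial perturbation (harmonics 3, 5, 7; amplitude =
`asymmetryWarp`; odd harmonics break mirror symmetry without changing
area much). The interior is colored by angular palette sectors (1–4
linear-RGB modes) with multiplicative band-limited texture evaluated in
lesion-normalized coordinates — so texture grows *with* the lesion, like
tissue — normalized to unit amplitude so `textureAmp` is the actual
modulation depth. Channel noise is Gaussian in linear RGB and redrawn per
frame (a static noise field would be content that votes for zero motion in
the flow). Skin carries a static mottling texture (amplitude 0.08)
anchored to canvas coordinates: real skin is textured, and without it the
flow over skin is undefined rather than zero. The image may be blurred
(`borderBlurSigma`) to soften the border; the returned mask is the exact
pre-blur boundary, and the analytic ground truth records area, the extent
along the major axis, palette and warp.

Progressions interpolate every property between a start and an end spec
under a shared structural seed (same harmonics and texture phases: the
same lesion, evolving), add a per-frame illumination drift to exercise the
normalization, and attach a sigmoid nevus-confidence series.

The `presetNevusToMelanoma()` conditions encode a coherent malignant
transition at 20 frames: boundary warp 0.02 → 0.4, border blur 4 → 1 px
(simulated melanomas tend to darken and sharpen), diameter +25%, one brown
mode drifting apart into three chromatically distinct modes
(reddish-brown, grey-brown, blue-grey — the classic variegation tones) at
constant sector fractions (0.4, 0.4, 0.2), texture 0.15 → 0.3 and noise
0.01 → 0.03, skin tone (160, 130, 110) sRGB, illumination drift
(+10, +8, +6) sRGB, confidence 0.97 → 0.08. Three of these choices are
load-bearing for a *continuous* dispersion trajectory and are worth
recording. (1) New color modes emerge by drifting away from the base color
rather than appearing fully formed: padded sectors initially share the
base color, which also makes the start fraction split a free gauge that is
pinned to the end fractions, so sector geometry is constant and only
colors move. (2) The drift is chromatic at near-constant luminance, so the
mode-separation axis is orthogonal to the texture's luminance axis: the
dip gate detects the split while the modes are still close, where the
within/between-cluster handoff is numerically small. (3) The moderate
skin–lesion contrast keeps the blurred boundary ring close to the interior
colors, so the ring does not read as a separate color mode that flickers
in and out of the gate. Under these conditions the rising metrics
(asymmetry, border gradient, color dispersion) increase monotonically and
correlate strongly and negatively with the decaying confidence — the
qualitative signature the package is designed to detect.

What passing these tests does *not* show: the generator has no pigment
network, globules, streaks or hair, no vignetting or specular highlights,
no registration error, and its palette sectors are angular wedges rather
than organic pigment fields. Results on generator output demonstrate the
correctness and internal consistency of the measurements, not clinical
validity on dermoscopic photographs.

## Problem sizes and determinism

The test bed uses 160 px canvases with lesion radii of 25–42 px, 8–20
frame sequences, 50-lesion parameter-recovery sweeps and 100-trial
cluster-count recovery runs; these sizes were chosen as the smallest at
which every geometric quantity (contour sampling, moment ellipses,
SSIM windows) is comfortably resolved. All randomness — generator
structure, per-frame noise, dequantization jitter, k-means restarts, the
dip test's Monte-Carlo null — is derived from explicit seeds, and the
pipeline derives per-stage seeds from one master seed by a stable hash, so
any result in this package is reproducible bit for bit from its
configuration.

## Known limitations

- Frames must be pre-registered; there is no motion compensation, and
  camera shake would read as lesion change.
- The dispersion score inherits the within-cluster definition's
  discontinuity at unimodality-gate flips; on borderline multimodal data
  the trajectory can step where k changes.
- The dip test's Monte-Carlo null is calibrated against uniform samples
  (the standard choice); for heavily tied data the statistic is slightly
  conservative-to-liberal depending on where atoms sit, which the
  dequantization jitter largely neutralizes.
- SSIM-based asymmetry reads sensor noise as dissimilarity; compare scores
  only across frames of comparable noise level.
- Optical flow over textureless regions is undefined; the synthetic skin
  texture masks this in tests, but flat, overexposed or heavily shaved
  regions in real imagery will produce unreliable vectors there.
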