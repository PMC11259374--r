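---
title: "Coil-guided collimation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coil-guided collimation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilcollim)
```

## The problem

During endovascular treatment of cerebral aneurysms, platinum embolization
coils are deployed under continuous X-ray fluoroscopy. Two dose problems
arise. First, the irradiated field is usually far larger than the region the
operator actually needs to see — the coil and its immediate surroundings —
so the dose-area product (DAP), the standard proxy for stochastic radiation
risk, is unnecessarily high. Collimating tightly around the coil reduces it.
Second, the coil itself is an extreme absorber: if it sits inside the
measurement field of the automatic exposure-rate control (AERC), the
controller interprets the dark coil as an obese patient and drives tube
output up, raising reference-point air kerma sharply. Both problems are
solved by *detecting* the coil: its bounding box defines the collimator
aperture, and its pixel region can be excluded from the AERC measurement
field.

`coilcollim` implements this workflow at desk scale. Clinical angiography
frames are proprietary, so a seeded phantom generator stands in for them;
the detection core is a classical multi-threshold blob detector (learned
detectors plug in through the same backend contract); and a deliberately
minimal AERC/dose model reproduces the *structure* of the dose experiments —
their orderings, ratios and test statistics — rather than any
hardware-calibrated absolute values.

## The phantom generator

`render_frame()` builds a line-integral attenuation map
$L(x)$ and converts it to unit-output detector signal $S(x) = e^{-L(x)}$
(higher stored value = more signal; coils are dark — stated once here, used
everywhere). The map is a sum of:

* a skull-like background: a soft-edged ellipse plus a three-component
  low-frequency cosine field, scaled by `background_attenuation_scale`;
* coil wires: each coil adds `coil_attenuation` per covered pixel. Three
  geometries are available — a tightly packed, jittered Archimedean spiral
  (`"spiral"`, ring spacing 1.5 wire thicknesses, the default: a packed
  coil reads as a nearly solid dark mass on radiographs), a filled disk
  (`"disk"`, the idealized fully packed mass), and a sparse self-crossing
  random walk (`"irregular"`, a loose framing coil that encloses mostly
  background — the blob detector's known hard case);
* catheter/guidewire distractors: smooth splines with attenuation well
  below the coil's.

Poisson noise is applied at `noise_poisson_scale` photons per unit signal,
then a gamma transform emulates imperfect intensity windowing, and the
collimator shutters are rendered as exact zeros (an idealization that makes
shutter auto-detection exact and testable). Ground truth is the tight
axis-aligned hull of each coil's rendered pixels, in 0-based half-open
coordinates.

Defaults are free parameters chosen once for plausibility, not calibrated
values: 640×640 px at 0.2 mm pitch (typical flat-panel detector), 32 px
shutter margins, coil radius 18–45 px (3.6–9 mm, a realistic packed-coil
mass), `coil_attenuation = 4` (about 2 % transmission — platinum-like),
distractor attenuation 0.6, `noise_poisson_scale = 2000`. The phantom does
**not** model calibrated X-ray spectra, scatter, detector MTF, or biplane
projection pairing; passing tests on phantoms therefore demonstrates the
pipeline's internal correctness and its behavior under the rendered
contrast regime, not clinical detection performance.

## Frame preparation

`prepare_frame()` chains the standard preparation steps: flip correction,
then counter-clockwise quarter-turn rotation (flip-then-rotate order is
fixed and documented; any fixed order is consistent as long as writer and
reader agree), collimator cropping from stored geometry (auto-detected from
the exact-zero border only as a fallback), anisotropic bilinear resize to
512×512 (no letterboxing — the simplest mapping with exact box arithmetic),
and standard-scaler normalization with the *population* standard deviation.
Normalization is applied after the resize so the prepared frame is
zero-mean/unit-variance to machine precision; a constant frame maps to
zeros with a warning rather than NaN, keeping degenerate fixtures
deterministic. Boxes ride along with the exact affine transform and are
rounded outward (floor minima, ceiling maxima), so no ground-truth pixel is
ever lost; the recorded transform is invertible.

## The blob detector

`detect_blobs()` implements the five-step classical detector with dark
polarity fixed (coils absorb):

1. Gaussian blur with `gauss_sigma = 9` — implemented as an exact separable
   convolution with reflect-101 boundary so constant images are preserved
   and small test fixtures blur cleanly;
2. binarization at each threshold of a sweep;
3. 8-connected components per binary image as candidate blobs (centroid +
   area), gated to `[min_area, max_area]`;
4. grouping of candidates across thresholds whose centroids fall within
   `min_dist_between_blobs` (10 px) of a group's area-weighted center —
   which also merges near-coincident blobs within one threshold;
5. a final gate: mean member area inside `[min_area, max_area]` and
   presence at `min_repeatability = 2` or more thresholds. Keypoint radius
   is `sqrt(support_area / pi)`; ties are broken by support area, then row,
   then column, for full determinism.

The sweep limits default to the blurred frame's 1st–60th intensity
percentiles with 64 evenly spaced levels — percentile anchoring makes the
sweep invariant to monotone windowing. Two parameters matter in deployment
and are derived from the expected coil sizes by
`blob_params_from_truth()`, mirroring the field rule that the smallest and
largest expected coil bound the admissible blob area:

* the area gate, in *blurred-blob* units:
  $[\,0.25\,\pi r_{\min}^2,\; 1.5\,\pi (r_{\max}+\sigma)^2\,]$, because the
  blur inflates a coil of half-side $r$ into a basin of radius up to about
  $r+\sigma$;
* the lower sweep quantile: a sweep anchored at the 1st percentile of a
  512×512 frame already selects ~2 600 pixels, more than a small coil's
  deep core, which biases the area estimate upward; the quantile is
  therefore lowered to the core's area fraction
  $0.25\,\pi r_{\min}^2 / N_{px}$ when that is smaller.

The detector emits no confidence estimate, so every detection carries the
constant score 1 — a documented limitation of the classical approach;
learned backends supply real scores through the same
`detect(frame) -> detections` contract, and a backend error is contained
(warning + empty result) rather than crashing the pipeline.

On dense coils the detector recovers a single keypoint whose circumscribed
box overlaps ground truth comfortably; on sparse irregular coils the
blurred basin is shallow and fragmented and localization degrades — the
test suite reproduces this failure mode deliberately. Catheter crossings
can create coil-sized dark spots and hence false positives; that is the
classical detector's real weakness and the reason a learned backend slot
exists.

## Collimation planning

`plan_aperture()` takes the tight hull of all accepted detections (real
collimators are single rectangles, so multi-coil frames are aggregated by
hull), scales width and height *multiplicatively* about the center by
`scale_factor`, and clips to the field. The expert margin is genuinely a
free operational parameter; 1.5 is the package default. Scaling could also
be read as additive padding; the multiplicative form was chosen because it
is scale-free across coil sizes, and this is flagged as an interpretation.
With no accepted detection the full field is returned flagged `"manual"` —
collimation stays with the operator, never silently guessed.

## The AERC/dose model

`simulate_exposure()` uses a deliberately minimal one-parameter exposure
model: tube output is scaled by $k = S^\ast / \overline{s}_M$ where
$S^\ast$ is the target mean detector signal and $\overline{s}_M$ the mean
unit-output signal over the measurement field $M$; then

$$\text{kerma} = k \cdot c \quad [\text{mGy}], \qquad
  \text{DAP} = \text{kerma} \times \text{area} \quad [\mu\text{Gy·m}^2],$$

with the identity DAP = kerma × 1000 × area(m²) holding exactly in every
report. A real controller regulates several coupled parameters
(tube voltage, current, pulse width, filtration); the single-knob model is
the minimal one that preserves everything the package asserts —
*orderings and ratios*: excluding a non-negative absorber from $M$ can only
lower $\overline{s}_M^{-1}$, so coil-aware kerma never exceeds coil-unaware
kerma, with equality at zero coil attenuation; a strict-subset aperture at
equal kerma strictly lowers DAP. Absolute mGy values depend on the
calibration constant and are not comparable to any hardware. The coil
exclusion mask is taken from detection boxes (rectangular exclusion),
matching how a real system would consume the detector's output; if the
exclusion empties the measurement field the simulator falls back to the
full aperture with a warning. The real measurement-field geometry of
clinical systems (central dominant zones) is proprietary; full-aperture-
minus-mask is the configurable stand-in.

`run_experiment1()` compares manual (default: full collimator opening)
against automatically planned apertures frame by frame and tests the two
DAP samples with the Mann–Whitney U test. `run_experiment2()` produces the
three-setting report — full field, coil-unaware, coil-aware — plus the
kerma/DAP reductions; `dose_reductions()` performs the same arithmetic on
recorded bench readings, two sets of which ship in `inst/extdata/`.

## Evaluation stack

IoU uses half-open box areas (touching boxes are disjoint). Average
precision follows standard single-class VOC semantics: score-ordered greedy
matching, one match per ground-truth box, all-point interpolation (area
under the precision envelope; the classic 11-point variant is available via
`method = "eleven_point"`). A dataset with no ground-truth boxes has
undefined AP and errors rather than returning a misleading 0 or 1.
`map_at()` keeps APs at different IoU thresholds distinct; with the single
"coil" class the per-class mean equals AP. "Mean IoU" dispersion is
reported over ground-truth instances (best detection IoU per box, 0 when
none overlaps) — stated explicitly because per-fold standard deviations are
otherwise ambiguous.

The patient-wise k-fold split shuffles *patients*, not frames: every
patient lands in exactly one validation fold, fold sizes differ by at most
one patient, and frames follow their patient, so 13 patients over 5 folds
always gives validation folds of 2 or 3 patients and no patient leakage.

The Mann–Whitney U statistic counts pairs $x_i > y_j$ plus half the
cross-group ties, so complete separation of $n_1 = n_2 = 5$ samples gives
$U = 25$ and identical samples give $U = n^2/2$. P-values are exact (via
the null permutation distribution) when both samples have ≤ 10
observations and the pooled sample is tie-free, otherwise the tie-corrected
normal approximation with continuity correction is used; the method is
recorded in the result, and the test suite checks the exact branch against
a full enumeration oracle.

## Numerical choices and degenerate inputs

* Coordinates are 0-based and half-open everywhere, including the VOC-style
  XML (recorded in each file, since classic VOC is 1-based inclusive).
* A (near-)uniform frame yields an empty auto-derived threshold sweep and
  zero keypoints; an explicitly inverted sweep errors.
* Frame rendering, preparation, detection and the pipeline are
  deterministic given the seed; every RNG use is locally scoped so library
  calls do not perturb the caller's RNG state.
* 16-bit TIFF output quantizes intensities to ~1.5e-5; all in-memory paths
  are double precision.

## Problem sizes used by the checks

The structural unit tests run on reduced phantoms (160–192 px frames); the
acceptance-style checks use the full study conditions: a 160-frame,
13-patient dataset for evaluation and fold splitting, 50 full-size
(640×640 → 512×512) dense-disk phantoms for detector recovery, 1 000
randomized scenes for the dose orderings, and the bundled five-pair and
three-setting bench readings for the statistics. These sizes were chosen as
the smallest at which each claim is meaningfully exercised.

## Known limitations

* The phantom's contrast regime is chosen, not measured; absolute detector
  performance numbers on phantoms say nothing about clinical images.
* The blob detector confuses coil-sized catheter crossings with coils and
  degrades on sparse framing coils; both behaviors are reproduced in tests
  rather than hidden.
* The dose model's absolute values are arbitrary up to its calibration
  constant; only orderings, ratios and reductions are meaningful.
* Multi-class evaluation beyond the single "coil" class is out of scope.
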