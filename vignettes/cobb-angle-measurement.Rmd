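---
title: "Measuring scoliotic curvature from vertebral boxes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring scoliotic curvature from vertebral boxes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobbcurve)
```

## The measurement problem

Scoliosis severity is quantified by the Cobb angle: on an anteroposterior
radiograph, the angle between the superior endplate of the uppermost
vertebra involved in a curve and the inferior endplate of the lowest.
Diagnosis requires an angle strictly above 10°; 10–25° is graded mild,
25–45° moderate, and above 45° severe. Manual measurement is the clinical
gold standard but is reader-dependent; automated pipelines instead detect
each vertebral body, reduce it to a bounding box and its center, and
measure curvature from a smooth midline fitted through those centers.

`cobbcurve` implements the measurement half of such a pipeline: everything
downstream of vertebra detection, plus a classical (non-learned) detector
and a synthetic phantom generator so that every stage can be validated
against analytically known ground truth without clinical images.

## The model

Vertebra centers $(x_i, y_i)$, ordered superior to inferior, are fitted by
ordinary least squares with a polynomial midline

$$x = f(y) = a_n y^n + a_{n-1} y^{n-1} + \dots + a_1 y + a_0,$$

with the vertical pixel coordinate $y$ as the independent variable — the
spine is quasi-vertical in this projection, so $x(y)$ is the single-valued
parameterization. Internally the fit uses $y$ rescaled to $[-1, 1]$ for
conditioning; every exposed quantity is in pixel units with the chain rule
applied through the rescale.

Inflection points — real roots of $f''$ with a sign change — partition the
spine into curve segments that each bend one way. The Cobb angle of a
segment bounded by $y_u < y_l$ is

$$\theta = \lvert \arctan f'(y_u) - \arctan f'(y_l) \rvert,$$

which equals the classical endplate construction because the angle between
two lines equals the angle between their perpendiculars. The end vertebrae
of a segment are those whose centers lie nearest its boundaries (ties
broken toward the segment interior), and a configuration flag
(`tangent_at`) chooses whether tangents are evaluated exactly at the
segment boundaries (default) or at the end-vertebra centers.

### Curve pattern and severity

The classifier is a small decision tree on the superior ("upper") and
inferior ("lower") reported angles: no angle above 10° means no scoliosis;
exactly one angle above 10° is thoracic when the upper angle is the larger
and lumbar otherwise; two angles above 10° are thoracolumbar when the
curves deviate toward different sides and combined when toward the same
side. That same-side/different-side assignment is the reverse of the most
common clinical usage; `clinical_convention = TRUE` swaps the two labels.
Severity is graded on the maximum reported angle. The printed bands
overlap at 25 and 45; the default convention makes each band
upper-inclusive (25° is mild, 45° moderate), consistent with the strict
">10°" diagnosis rule, and `convention = "lower"` assigns shared edges to
the higher band.

### Which side is a curve on?

Consecutive inflection-bounded segments alternate the sign of $f''$ by
construction, so "side of the curve" cannot be the sign of the second
derivative — that would make a two-curves-same-side pattern (the
"combined" branch) unrepresentable. Instead the side of a segment is the
sign of its apex's deviation from the chord joining the midline's values
at the two domain endpoints. The apex is the root of $f'$ inside the
segment (the point of maximal lateral excursion) when one exists,
otherwise the boundary with the smaller $|f'|$; a degenerate apex sitting
exactly on the chord takes side $+1$ by convention.

## The phantom generator

`phantom_spec()` / `generate_phantom()` render an ordered column of bright
quasi-rectangular bodies whose centers lie on a known polynomial midline,
with Gaussian blur, additive Gaussian noise, and controllable two-level
contrast, plus exact box annotations. `analytic_cobb()` differentiates the
generating polynomial in closed form (inflections from the
companion-matrix root solver, screened for genuine sign changes), so the
phantom's Cobb angles are known exactly — no fitting involved.
`phantom_from_angles()` inverts the construction: it solves for
coefficients realizing a requested pattern (straight; one quadratic arc
with its apex at a chosen span fraction, default 0.35, a thoracic apex;
or an S-shaped cubic with prescribed superior and inferior angles).

Default geometry is chosen to emulate a full-spine radiograph at the
900×1900 working size: 15 vertebrae (17 for thoracic+lumbar coverage) of
110×80 px with a 22 px gap, foreground/background intensities 0.85/0.25,
1 px blur. Spacing jitter, lateral center jitter and per-body rotation are
available for stress tests and default to zero. What the phantom does
*not* emulate: ribs, pedicles and the pelvis, vertebral rotation, exposure
gradients, or 3D projection effects. Passing phantom-based tests therefore
demonstrates correctness of the measurement geometry, not detector
robustness on clinical images — the detector is deliberately the
replaceable stage.

## Image preparation

Radiographs are standardized to 900×1900 by an aspect-preserving bilinear
rescale followed by symmetric zero-padding. Letterboxing rather than
stretching matters: anisotropic stretching by factor $s$ would multiply
every slope by $s$ and bias every angle. The scale and pad offsets are
recorded so detections map back to native coordinates.

The contrast adjustment a radiologist performs interactively in a DICOM
viewer is reproduced by three deterministic methods — percentile
windowing (default, percentiles 2–98), gamma correction, and CLAHE (8×8
tiles) — all monotone in intensity so bone/background polarity is
preserved. Automatic parameter selection is out of scope by design;
parameters are user-supplied.

## Detection

Two routes produce the ordered box sequence. Annotation ingestion reads
JSON, CSV or YOLO-style normalized labels, merges duplicates (IoU > 0.8,
higher confidence wins, ties to the larger area) and sorts by center.
The classical detector thresholds (Otsu by default), opens with a 3×3
kernel, labels connected components, gates them by area and aspect ratio,
and drops lateral outliers against the running median of neighboring
centroids (60 px default at standard size). The area gates are
$[0.25, 4]\times$ a reference area taken as the *area-weighted median* of
component areas: with a plain median, a cloud of small surviving noise
specks can outnumber the vertebrae and drag the upper gate below the
vertebra area, while specks carry negligible total area and so cannot
move the weighted median.

Endplate tilts are refined with a straight-line Hough transform (ρ
resolution 1 px, θ resolution 1°, restricted to ±30° of horizontal) run
separately over the upper and lower halves of a padded window per box.
The accumulator is fed one sub-pixel edge point per column — the
gradient-magnitude centroid of the strongest vertical-gradient response —
because raw thresholded edge pixels staircase-quantize a near-horizontal
edge into whole rows and snap small tilts to 0°. Sub-degree tilt precision
comes from parabolic interpolation across the θ bins. The endplate route
(`cobb_from_endplates()`) is a cross-check; the midline-tangent route is
primary, since endplate identification is the classical weak point.

## Numerical choices

* Fitted inflections are located by a 1 px sign-change scan refined by
  bisection to $10^{-6}$ px; roots within 0.5 px of a domain endpoint are
  dropped as boundary-degenerate (the analytic route applies the same
  margin).
* $|f''|$ and $|f'|$ below $10^{-12}$ px$^{-1}$ are treated as zero: an
  exactly straight spine fitted at degree 5 leaves least-squares residue
  around $10^{-14}$ that would otherwise produce spurious sign changes.
  Real curvature is at least eight orders of magnitude above this clamp.
* The default fit degree is 5 (supports up to three inflections:
  thoracic, lumbar and a transitional curve), reduced to $n-1$ when fewer
  centers are available; an explicitly requested degree that the point
  count cannot support is an error, and rank deficiency lowers the degree
  with a warning.
* Extrapolation outside the fitted domain is rejected rather than
  returned.
* Measurements are reported to 0.01° in the JSON report.

## Validation strategy and problem sizes

Every stage is tested against an independent oracle: closed-form
differentiation for constructed cubics and quadratics; a dense-grid brute
force (0.01 px sampling of $f''$) for random polynomials up to degree 6;
the phantom's analytic truth for the full pipeline. Invariants are tested
as properties: mirror equivariance (angles preserved, sides flipped),
uniform-scale invariance to $10^{-9}$°, vertical-shift equivariance, the
triangle inequality of Cobb angles across nested boundaries, severity
monotonicity, and exhaustive grid equivalence of the classifier against a
literal transcription of its decision tree.

The recovery studies use 100 noise-free random polynomial phantoms
(degree ≤ 5; every recovered angle within $10^{-6}$° of truth) and 200
seventeen-vertebra single-curve phantoms with true angles uniform in
[15°, 50°] and 2 px lateral center jitter, where at least 95% of runs must
land within 3° of truth. Under these conditions the long-run rate is
about 96.8% (measured over 1000 runs), so the 200-run check sits about
1.4 binomial standard deviations above its bound; these sizes keep the
full suite under a minute of compute while leaving the checks sharp.

## Known limitations

The classical detector assumes vertebrae are the dominant bright blobs —
adequate for phantoms and well-windowed radiographs, not for cluttered
clinical images; its interface is the pluggable point for a learned
detector. Vertebral rotation is not assessed, boxes are axis-aligned,
and sagittal-plane angles (kyphosis/lordosis) are out of scope. More than
three curves would need a higher fit degree than the supported maximum
of 6. The comparison module reproduces summary and paired-test structure
only; reliability coefficients (ICC, Bland–Altman) are natural extensions
not included.
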