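---
title: "Quantifying enamel demineralization from QLF images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enamel demineralization from QLF images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qlfquant)
```

## The measurement problem

Under high-intensity blue light, sound enamel auto-fluoresces; demineralized
enamel fluoresces less, so an early (white-spot) lesion appears as a dark
patch in a quantitative light-induced fluorescence (QLF) capture. The
quantity of clinical interest is the *percent fluorescence loss* at each
lesion pixel relative to what that pixel *would* have emitted were the
tissue sound — a value that cannot be observed and must be reconstructed
from the sound tissue surrounding the lesion. `qlfquant` implements that
reconstruction, a noise-robust maximum-loss readout, and a calibration that
converts percent loss into an estimated histological lesion depth in µm.

## Sound-value reconstruction

The user supplies a polygon region of interest (ROI) whose edges all lie on
sound tissue, drawn closely around the lesion. For an interior pixel $M$ at
$(x_m, y_m)$ the reconstruction is a two-step, two-dimensional linear
interpolation from the ROI border:

1. **Horizontal step.** With $g$ and $h$ the nearest border pixels left and
   right of $M$ on its row,
   $$L_m(x) = L_g + (L_h - L_g)\,\frac{x_m - x_g}{x_h - x_g}.$$
2. **Vertical residual step.** With $e$ and $f$ the nearest border pixels
   above and below $M$ on its column, the same horizontal rule evaluated on
   rows $y_e$ and $y_f$ gives interpolated values $L_e(i)$, $L_f(i)$ at the
   columns of $e$ and $f$; the residuals $\Delta L_e = L_e - L_e(i)$ and
   $\Delta L_f = L_f - L_f(i)$ are blended vertically,
   $$L_m(y) = \Delta L_e + (\Delta L_f - \Delta L_e)\,
     \frac{y_m - y_e}{y_f - y_e},$$
   and the reconstructed sound value is $L_m(i) = L_m(x) + L_m(y)$.

The absolute loss is $\Delta L_m = L_m(i) - L_m$ and the percent loss is
$100\,\Delta L_m / L_m(i)$. The scheme's defining analytic property — the
package's most important invariant, verified by property tests — is
*exactness on affine fields*: if the intensity is any plane $a + b_x x +
b_y y$, step 1 is exact along rows and both residuals vanish, so
$\Delta L \equiv 0$ over the whole interior.

Two forms are exposed. `interpolate_rectangle()` is the reference form on an
axis-aligned rectangle: raw edge intensities, step-2 interpolation running
between the rectangle's corners. `interpolate_polygon()` generalizes it to
arbitrary simple polygons with two noise-hardening modifications: every
border pixel's intensity is first replaced by the mean of its 3 × 3
neighborhood (clipped at the image boundary — averaging over the available
pixels avoids inventing intensities outside the image), and anchors are the
nearest border pixels bounding the pixel's *own* row/column span, so in a
non-convex ROI each lesion lobe is reconstructed from the sound tissue
adjacent to it.

### Generalizing the step-2 anchor rows

In the rectangle form, the horizontal interpolation at the top/bottom edge
pixels runs between the rectangle's corners — the *endpoints of the border
row*. The polygon analogue implemented here interpolates between the
endpoints of the maximal contiguous run of border pixels containing the
anchor on its row; when that run is a single pixel (a steep edge crossing
the row), the interpolated value equals the observed one and the residual
is zero. This is the generalization that degenerates *exactly* to the
rectangle algorithm for rectangular polygons, which the test suite checks
by cross-implementation equivalence on constant-bordered fields.

### Rasterization choices

Pixels are addressed 0-based with x = column, y = row and centers at
integer coordinates. Interior membership uses the even-odd rule on pixel
centers (deterministic for the non-convex ROIs that "closely adapted"
polygon drawing produces); border pixels come from supercover line
rasterization of each edge, which includes both side pixels at exact
corner crossings. Supercover is what guarantees the geometry invariant the
interpolation relies on: every interior pixel finds a border anchor in all
four axis directions, with no diagonal gap for a row or column to escape
through. Sub-pixel (real-valued) vertices are accepted and resolved at
rasterization. Self-intersecting polygons, polygons exceeding the image
bounds, and polygons with empty rasterized interiors are rejected as
errors, not repaired.

Negative losses (a pixel brighter than its reconstruction — specular
highlights, remineralization) are retained as negative values in the maps
rather than clamped, but are never candidates for the maximum.

## The robust maximum

A single-pixel maximum of the percent map is fragile: QLF sensors produce
occasional isolated "cold spots" whose apparent loss is an artifact.
`robust_max_loss()` ranks valid interior pixels by descending percent loss
(ties resolved to the smaller row-major index, making the procedure fully
deterministic) and inspects candidates in order. A candidate whose value
exceeds the mean of its 3 × 3 neighborhood (clipped to valid interior
pixels) by more than a fraction `rel_tolerance` of itself is rejected as a
cold spot; the walk continues until a candidate agrees with its
neighborhood, and the *neighborhood mean* — not the raw pixel — is
reported as the maximum loss.

Two design choices matter here:

* **The rejection threshold is relative** (`rel_tolerance`, default 0.20).
  A scale-free criterion keeps the test meaningful across bit depths and
  lesion severities; 0.20 is conservative in the sense that a genuine
  smooth maximum sits only a few percent above its 3 × 3 mean and always
  passes, while an isolated spike exceeds it many-fold. Whether the
  original procedure used a fixed margin or a statistical test is not
  recoverable, so the threshold is an explicit, documented parameter
  rather than a guess at intent.
* **Rejected pixels are excluded from subsequent neighborhood means.**
  Without this, a rejected spike would still contribute up to one ninth of
  its magnitude to the accepted neighbor's mean, quietly re-importing the
  artifact that was just identified. With it, the reported maximum is
  insensitive to the spike's magnitude entirely. The iteration also
  continues past the second-ranked candidate if needed — multiple cold
  spots degrade gracefully — and degenerates to a single second-candidate
  check when only one spike exists.

The lesion area is the count of valid pixels at or above `area_threshold`
(default 5 % loss, a conventional lesion-area cutoff exposed as a
parameter).

## Depth calibration

The packaged calibration set (`calibration_pairs()`) holds six paired
measurements from demineralized enamel specimens: largest histological
caries depth (µm, from polarized-light micrographs of sections) and
maximum percent fluorescence loss from the corresponding QLF analysis.
`fit_calibration()` fits ordinary least squares of **loss (%) on depth
(µm)**. The source material states the axis orientation both ways in
different places; only this orientation reproduces all of the printed
statistics (slope 0.32, intercept 0.17, r = 0.9696, t = 7.93, F = 62.86),
so it is the one implemented, and depth estimates are obtained by inverse
prediction rather than by fitting the reversed regression. p-values come
from exact t and F distribution functions, not tables. For a single
predictor F = t² algebraically, so the two tests share one p-value; the
package reports that common value (0.0014 here at 4 decimals) rather than
reproducing the two slightly different published roundings.

`estimate_depth()` inverts the line, with the standard approximate
inverse-prediction interval for a single new observation,
$$\hat x_0 \pm t_{\alpha/2,\,n-2}\,\frac{s}{|\hat\beta_1|}
  \sqrt{1 + \tfrac1n + \frac{(\hat x_0 - \bar x)^2}{S_{xx}}}.$$
Estimates below zero are returned with a warning — they signal a measured
loss below the calibration range, not a physical depth.

```{r calibrate}
cal <- fit_calibration(calibration_pairs())
cal
estimate_depth(cal, 25)
```

## The phantom generator

`generate_phantom()` builds synthetic tooth images for end-to-end
validation: a smooth sound field (constant, affine plane, or a quadratic
dome standing in for natural crown curvature), an embedded elliptical
lesion with a cosine-taper radial profile (smooth, compactly supported,
unambiguous peak), optional Gaussian sensor noise, and optional
single-pixel hot/cold spots. The lesion is *multiplicative* —
`image = sound × (1 − loss/100)` — so the ground-truth percent-loss grid
is exact by construction even on curved fields. Intensities are rounded to
integer sensor counts and clipped to the bit-depth range, as a real
capture would be.

Defaults describe one fixed, realistic study condition: an 80 × 80 8-bit
capture, an affine sound field `180 + 0.3 x + 0.2 y` (a bright field with
a gentle illumination gradient), a centered lesion of radii 16 × 13 px
with 25 % peak loss, and noise off unless requested; validation runs use
`noise_sd = 1` intensity unit (≈ 0.5 % of the sound level), consistent
with the single-count noise of an 8-bit sensor. The suggested ROI is a
regular octagon whose inradius clears the lesion support by 2 px and whose
vertices stay 1 px inside the image so every border smoothing window is
complete.

What the phantoms deliberately do **not** emulate: optical light transport
in enamel (scattering, translucency, surface wetness), staining, specular
highlights, or geometric distortion. Passing the phantom suite therefore
demonstrates the *algorithmic* properties — exact reconstruction where the
theory says exact, bounded curvature bias, cold-spot immunity — not
photometric accuracy on clinical images, which only a physical validation
can establish.

## Validation problem sizes

The property and acceptance tests run at sizes chosen to exercise the
mathematics fully while keeping the suite quick: 100 random affine 32 × 32
images with random star-shaped polygons for the exactness property
(tolerance 1e-9 relative); 50 random 16 × 16 images against a direct
scalar transcription of the interpolation equations (1e-9); 20 seeded
80 × 80 phantoms with peaks drawn from 10–30 % for recovery (observed
|bias| ≤ 1 and RMSE ≤ 2 percent points) and for the cold-spot stress test
(robust estimate moves < 2 points while the raw single-pixel maximum
overshoots truth by > 50 %). `scripts/acceptance.R` recomputes all of
these from scratch at any seed.

## Known limitations

* The reconstruction is strictly the two-step *linear* scheme; on strongly
  curved sound fields it carries a bias (bounded in tests at < 3 percent
  points on a pronounced quadratic dome). Higher-order reconstruction is
  out of scope by design.
* The calibration rests on six specimen pairs; the inverse-prediction
  interval is honest about that (≈ ±18 µm at 95 % mid-range), and
  extrapolation beyond ~11–30 % loss leaves the calibrated range.
* 16-bit output must be written as TIFF; the PNG writer is 8-bit.
* The loss-map TIFF export stores affinely rescaled layers (TIFF samples
  live in [0, 1]); the CSV export is the lossless record.
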