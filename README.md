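# qlfquant

Quantifies early enamel demineralization from quantitative light-induced
fluorescence (QLF) images, for cariology researchers and software working
with in-vitro or intraoral QLF captures.

Demineralized enamel fluoresces less than sound enamel under high-intensity
blue light, so an incipient (white-spot) lesion appears as a dark patch.
The loss at a lesion pixel is defined against the fluorescence the pixel
*would* show if the tissue were sound, which must be reconstructed from the
surrounding sound tissue. `qlfquant` implements:

- **Sound-value reconstruction** by two-step two-dimensional linear
  interpolation inside a user-drawn polygon ROI whose edges lie on sound
  tissue. For interior pixel *M*, step 1 interpolates horizontally between
  the row's border anchors *g*, *h*:
  `L_m(x) = L_g + (L_h − L_g)(x_m − x_g)/(x_h − x_g)`;
  step 2 forms the residuals `ΔL_e = L_e − L_e(i)`, `ΔL_f = L_f − L_f(i)`
  at the column anchors *e*, *f* (each `L(i)` from the same horizontal
  rule on the anchor's row), blends them vertically, and returns
  `L_m(i) = L_m(x) + L_m(y)`. Percent loss is `100 (L_m(i) − L_m)/L_m(i)`.
  The scheme is exact on any affine intensity field. Border anchor
  intensities are 3×3-smoothed to suppress sensor noise; the rectangle
  reference form of the original algorithm is also exposed.
- **A robust maximum-loss readout** that rejects isolated "cold spots":
  candidates are examined in descending order, a candidate standing more
  than a relative tolerance (default 0.20) above its 3×3 neighborhood mean
  is discarded (and excluded from later means), and the accepted
  candidate's neighborhood mean is the reported maximum.
- **Depth calibration**: ordinary least squares of percent loss (%) on
  histological lesion depth (µm) over a packaged set of six specimen
  pairs — `loss = 0.32·depth + 0.17`, r = 0.9696, t = 7.93, F = 62.86,
  p = 0.0014 — inverted by standard inverse prediction to estimate depth
  from a measured loss, with a confidence interval.
- **Fire-LUT rendering** of loss maps, a **synthetic phantom generator**
  with exact ground truth, and a **CLI** (`inst/cli/qlfquant.R`) with
  `analyze`, `calibrate`, `phantom` and `render` subcommands.

## Worked example

Generate a synthetic tooth with a known 25 %-peak lesion on a tilted
sound field, add unit sensor noise, and run the full pipeline:

```r
library(qlfquant)
ph  <- generate_phantom(phantom_spec(noise_sd = 1, seed = 5))
res <- analyze(ph$image, ph$roi)
res
#> Lesion metrics (robust maximum fluorescence loss)
#>   max percent loss : 24.38 % (3x3 mean at x=41, y=39)
#>   raw single-pixel max : 25.71 %
#>   cold spots rejected  : 0
#>   lesion area (>= 5 %) : 329 px
#>   mean loss over lesion : 13.45 %
#>   estimated depth : 76.5 um (95% interval 58.3 - 94.7 um)
max(ph$truth_percent)
#> [1] 24.84882
```

The robust maximum (24.38 %) is the 3×3 neighborhood mean at the accepted
peak — within half a percent point of the phantom's true maximum
(24.85 %), while the raw single-pixel value (25.71 %) rides the noise. The
depth estimate converts the measured loss through the packaged calibration
line: (24.38 − 0.17)/0.3165 ≈ 76.5 µm, with a 95 % inverse-prediction
interval reflecting the six-pair calibration's uncertainty.

The calibration itself:

```r
fit_calibration(calibration_pairs())
#> Depth-to-fluorescence-loss calibration (OLS, loss % on depth um)
#>   n = 6 pairs
#>   loss = 0.32 * depth + 0.17   (full precision: 0.316472, 0.171881)
#>   r = 0.9696
#>   t (slope, 4 df) = 7.93,  F (1, 4 df) = 62.86
#>   two-tailed p = 0.0014
```

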