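---
title: "Methods: image-based flowability metrics and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based flowability metrics and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powderflow)
```

## The measurement model

Microdynamic flowability testing discharges a small (<200 mg) powder
sample through an orifice under controlled mechanical motion and images
the resulting flow pattern against an illuminated background. Cohesive
powders resist the displacement and leave sparse, lumpy patterns; free
flowing powders spread widely and evenly. The package turns one such
grayscale image into two numbers.

**Flow Index.** FI is the percentage of the illuminated region of
interest (ROI) covered by powder: `FI = 100 · |powder| / |ROI|`. The
powder pattern is segmented by Otsu's method on the 256-bin intensity
histogram of the ROI. Under backlighting the powder silhouettes dark
against a bright background, so the powder is the class at or below the
threshold; frontlighting inverts that. `polarity = "auto"` compares the
mean intensity of an 8 px band along the ROI border with the ROI
interior: powder accumulates centrally below the orifice, so a brighter
border indicates backlighting.

**Agglomeration Ratio.** AG is the fraction of *darker* pixels within
the powder pattern: cohesive agglomerates are optically thicker than a
dispersed particle monolayer and transmit or reflect less light. A
second Otsu threshold is computed on the histogram restricted to the
powder mask, and AG is the dark-class area fraction. The denominator is
the powder-pattern pixel count, not the ROI, which makes AG independent
of FI.

Both segmentations assume a *bimodal* histogram. For FI the assumption
is mild (illuminated background vs. powder); for AG it frequently fails
— a non-cohesive pattern is a single intensity mode and any threshold
through it is meaningless. AG is therefore guarded by a separability
gate, described next.

## The bimodality gate

After the within-pattern Otsu split, the package computes an
Ashman-style separability statistic between the two resulting classes,

$$D = \frac{|\mu_1 - \mu_2|}{\sqrt{(\sigma_1^2 + \sigma_2^2)/2}},$$

and reports AG only when `D > bimodalityCut`; otherwise the histogram is
declared unimodal and AG = 0 with `bimodal = FALSE`.

The conventional clean-separation cut for Ashman's D is 2.0 — but that
convention applies to the parameters of *fitted mixture components*.
Here the moments come from the two truncated halves of the histogram,
which systematically inflates D: splitting a single Gaussian at its mean
gives class means ±0.80σ and class standard deviations 0.60σ, hence
D ≈ 2.65; a uniform histogram gives D ≈ 3.46. A cut of 2.0 would declare
essentially every histogram bimodal. The default is therefore
**4.0**, which rejects both of those unimodal shapes while genuinely
separated modes score far higher (two modes 60 gray levels apart with
within-mode spread of 5 levels give D ≈ 12; two pure spikes give
D = ∞). The cut is configurable (`bimodalityCut`) for imaging setups
with different noise characteristics.

## Numerical and interface choices

- **Otsu implementation.** The threshold maximises the between-class
  variance over all 255 cuts of a 256-bin histogram; ties take the
  lowest maximising cut, so results are deterministic. The test suite
  checks equality with an independent exhaustive search on random
  histograms.
- **16-bit images** are binned into 256 bins by integer division by 256,
  so thresholding behaves identically across bit depths; thresholds are
  reported on the original intensity scale (top of the selected bin).
- **RGB input** converts to Rec. 709 luminance (0.2126 R + 0.7152 G +
  0.0722 B) — the standard for digital camera output. Any convex
  weighting maps equal channels to the channel value.
- **Coordinates.** Pixels are 0-based, row-major, origin top-left;
  ROI rectangles are half-open `[x0, x0+w) × [y0, y0+h)` and are clipped
  to the frame, which makes intersection arithmetic unambiguous.
- **The ROI is an explicit input** (rectangle, mask image, or full frame
  by default). How the illuminated background boundary is delimited is a
  property of the instrument setup, not of the image statistics, so the
  package does not attempt automatic illumination detection.
- **Small-component suppression.** Connected powder components under
  4 px (4-neighbour connectivity) are removed before FI as sensor-noise
  specks; the default is small enough to be negligible at realistic
  pattern scales and is configurable (`minComponent`). No other
  morphology is applied — opening or closing would silently change FI.
- **Classification bands.** The published band table writes “>50”,
  “30–50”, “10–30”, “<10”, leaving the boundary values ambiguous. The
  package uses left-closed half-open intervals ([10,30), [30,50),
  [50,100]) so each boundary belongs to the better class and the four
  bands partition [0,100] exactly. Classification applies to the
  replicate mean FI, matching the one-class-per-material presentation;
  band edges are configuration (`flowBands()`), not measurements.
- **Degenerate inputs.** A contrast-free ROI yields an empty powder mask
  plus a warning flag rather than an error (FI = 0 is the honest
  answer); an empty powder mask makes AG undefined and errors when
  requested directly, while the composed `analyzeImage()` reports AG = 0
  flagged unimodal.

## PSD percentiles and span

Laser-diffraction exports give volume fractions per size class. The
package treats class values as **bin upper edges of a cumulative curve
starting at zero**, anchored at a lower edge extrapolated with the
spacing of the first two classes, and inverts the piecewise-linear curve
for the size at which cumulative volume first reaches p — interpolating
**linearly in log(size)** by default, since diffraction size classes are
log-spaced (`interp = "linear"` is available, and the conventions are
documented so other instrument exports can be mapped). Dv10 ≤ Dv50 ≤
Dv90 and scale equivariance hold by construction and are tested against
a fine-grid inversion oracle.

Span is the standard diffraction width measure (Dv90 − Dv10)/Dv50. With
replicates, percentiles and span are computed per replicate and then
aggregated as mean ± sample (n−1) standard deviation — not span of
averaged percentiles — matching per-measurement replicate statistics.
Recomputing span from published before/after-milling percentiles
reproduces the printed values (3.60, 3.28) to two decimals, which is the
only available validation of the formula choice.

## The synthetic scene generator

Real flow-pattern images from the instrument are not publicly available,
so validation rests on a seeded generator that emulates their geometry
and gray-level statistics:

- **Dispersed particles**: a homogeneous Boolean model — disk centres
  uniform in the frame, radii lognormal (median 4 px, log-sd 0.25,
  clamped at 2 px so particles survive rasterisation).
- **Agglomerates**: Thomas-type parent–offspring clusters — parents
  uniform, a Poisson number (mean 20) of member disks per cluster
  displaced by an isotropic Gaussian (σ = 7 px).
- **Placement control**: clusters are added until the agglomerate pixel
  target (`agglomerateFraction × targetCoverage × frame`) is reached,
  then dispersed disks until total coverage reaches the target; each
  disk adds at most ~50 px, so realised coverage overshoots by well
  under 2 percentage points (tested). A bounded attempt count turns an
  unreachable target into an error.
- **Rendering (backlight)**: background 230; dispersed powder 160;
  agglomerate pixels `100 · exp(−0.08 (m − 1))` where m is the number of
  covering cluster-member disks; Gaussian noise (default σ = 5 gray
  levels) then clipping to [0,255]. Frontlighting inverts the image.
  Dispersed powder renders as a *monolayer* — in-plane overlap of
  dispersed disks does not darken, because spread particles in the flow
  plane are one particle thick; only stacked cohesive material
  attenuates further. This keeps the dispersed mode at a single gray
  level, as the physics of a thin spread layer suggests, and keeps the
  dark class unambiguously agglomerate.
- **Ground truth** is *cluster membership*, not darkness: the label map
  marks pixels covered by any cluster-member disk as agglomerate,
  otherwise-covered pixels as dispersed. Truth must be independent of
  the rendering used to detect it.
- **Determinism**: each scene is generated under its own seed inside a
  scoped RNG (global RNG state is saved and restored), so identical
  parameters give byte-identical images and the session's random stream
  is untouched.

The default levels give mode separations of 70 (background–dispersed)
and ≥ 60 (dispersed–agglomerate) gray levels. These separations are
chosen to satisfy the method's own bimodality assumptions — the actual
gray-level statistics of instrument images are unknown. Consequently,
passing recovery tests demonstrate that the *metrics measure what they
claim on images obeying their assumptions* (FI within 2 percentage
points of true coverage, AG within 0.05 of the true agglomerate
fraction across coverage 5–50 % and agglomerate fraction 0–0.4); they do
not certify performance on images with poor contrast, uneven
illumination, or agglomerates whose gray levels overlap dense single
particles — the known failure mode of any single-threshold method.

One interaction constrains the intensity model: with three intensity
populations (background, dispersed, agglomerate), a single Otsu cut on
the full-frame histogram can isolate the darkest population instead of
separating powder from background if the agglomerate mode is very dark
and heavily populated. At the default agglomerate level (100) the
powder/background cut dominates across the tested grid (through
agglomerate fractions of 0.4 at 50 % coverage); pushing the agglomerate
level far darker (e.g. 60) flips the maximiser and FI collapses onto
the agglomerate area alone. This is a property of single-threshold
segmentation itself, worth knowing when configuring a real instrument's
lighting.

## Problem sizes and runtime choices

The validation grid in the acceptance tests uses 512×512 px scenes —
coverage {5, 15, 30, 50} % × agglomerate fraction {0, 0.2, 0.4} × 20
seeds (240 scenes, noiseless) — which runs in well under a minute on one
core. Unit and property tests use 64–192 px frames, chosen so each
individual property check stays at fixture scale while the acceptance
grid exercises realistic image sizes.

## Limitations

- FI and AG are relative measures at a fixed applied flow rate; the
  package does not model flow-rate dependence, nor compare samples
  statistically.
- AG interpretation differs by material class: for cohesive powders the
  dark fraction reflects cohesive lumping, for non-cohesive coarse
  materials it reflects darker coarse particles against fine bright
  ones. The package reports the number with its bimodality flag and
  leaves interpretation to the analyst.
- Single dense particles with agglomerate-like gray values are counted
  as agglomerate; disambiguating them needs shape or texture features
  beyond thresholding.
- The generator reproduces image statistics only — no particle motion,
  cohesion forces or discrete-element mechanics.
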