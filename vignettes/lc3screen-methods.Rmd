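---
title: "Methods: whole-organism autophagy screen analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-organism autophagy screen analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lc3screen)
library(dplyr)
```

## What this package computes

High-content screens for autophagy modulators in zebrafish larvae read out
autophagosome abundance as fluorescent LC3 puncta in the trunk musculature.
Because autophagosome counts conflate synthesis and degradation, flux is
measured by re-imaging the same larvae after blocking lysosomal degradation
with NH4Cl: a compound that raises flux increases puncta more strongly in
the blocked state. `lc3screen` implements the full analysis chain — larva
localization, puncta segmentation, vehicle normalization, flux ratios,
dose–response profiles with toxicity masking, E~max~ ranking and 4PL IC50
fits — plus the companion ratiometric (mito-QC, mtRosella, TMRM, JC-10) and
physiological (respirometry, worm activity) readouts, and a seeded
synthetic-data module that makes the whole chain testable without any raw
images.

## The puncta segmentation chain

For each acquisition the Z-stack (26 planes at 20x in the emulated design)
is reduced by **maximal projection**. The projection is then **smoothed**
by a 3x3 median filter followed by a Gaussian blur; the blur sigma
(default 10 px) is of the order of the larva half-width, so the smoothed
image is a body-background estimate containing no punctate signal. The
method names the smoothing only as serial operations; the median+Gaussian
pair with a heavy sigma is this package's concrete choice, exposed in
`lc3_config()$puncta`.

The **body mask** is a global binarization of the smoothed image (Otsu by
default; a fixed threshold is configurable), cleaned by area filtering
(components under `min_body_area`, default 5000 px^2, are dropped and the
largest survivor kept) and finally **shrunk** by a disc erosion
(`shrink_radius`, default 5 px) so the mask sits inside the true outline.
Because a global threshold on a blank well splits a unimodal noise
distribution and invents a "body", binarization is additionally gated by a
foreground/background contrast floor (above-threshold mean at least 1.5x
the below-threshold mean); a field failing the gate raises the
"no larva detected" condition that drives the displaced-larva exclusion.

The **subtracted image** is `max(projection - smoothed, 0)`, and puncta are
its connected components above `k x mean(smoothed over the body mask)`
with area at least `min_punctum_area` (default 4 px^2). The scale factor
`k` defaults to 1 — the body-covered mean is used directly — but is exposed
because real acquisitions may need `k != 1`; since the threshold is
proportional to the smoothed mean, puncta *counts* are invariant to global
intensity rescaling. Containment keeps only objects **fully inside** the
body mask by default (`centroid_inside` is the tolerant alternative for
objects at the body edge). The per-larva readout is the **relative puncta
area**: total puncta area divided by body area, dimensionless, reported
alongside px^2 and um^2 (px^2 x `pixel_size_um`^2) values.

Coordinates throughout are 1-based `(row, col)` with inclusive ROI bounds —
the natural R slicing convention.

### Larva localization

`locate_larvae()` finds up to three silhouettes per well (three embryos are
placed per well in the emulated design), takes each silhouette's long axis
from a principal-component decomposition of its pixel coordinates, and
anchors the analysis area a configurable `head_tail_offset` inward from the
head- and tail-side extremes. The offset and analysis-area size have no
method-derived values, so both are plain configuration with defaults chosen
for the synthetic geometry (40 px at the low-magnification scale). Larvae
touching the image border, or too short for the offset window, are flagged
and skipped rather than mismeasured. `process_well()` pairs larvae across
the pre/post acquisitions by nearest anchor distance (ties: smallest
distance, then lowest index) and emits explicit displaced-excluded records
for larvae seen in only one phase — exclusions are data, never silent
deletions, so group n's stay auditable.

## Screen analytics

Per-larva relative areas are normalized to the **vehicle mean of the same
plate and phase** (`normalize_to_vehicle()`). Whether each phase should be
normalized to its own vehicle or both to the baseline vehicle is genuinely
open; per-phase is the default and `normalization = "pre_vehicle"` the
alternative. The group summary is the mean (matching fold-change heatmap
semantics), with the median as a robust option. The **flux ratio** is the
post-NH4Cl fold change over the pre-NH4Cl fold change; when the same larva
is measured in both phases, per-larva paired ratios (vehicle-adjusted) are
also reported and are considerably less variable, since the larva-level
biological variation cancels.

**Dose–response profiles** carry fold changes at ascending doses with
per-cell toxicity flags. Toxicity is an *input* call (visual inspection in
the emulated workflow), not computed; **E~max~** is the maximum fold change
in the presence of NH4Cl over non-toxic doses only, and all-toxic compounds
are reported excluded rather than dropped. Ranking is by descending E~max~
with ties going to the compound achieving its maximum at the lower dose,
then to lexicographic order; the hit flag (default E~max~ >= 1.5) is
explicitly threshold-dependent since no principled cut exists. Inferential
statistics (ANOVA and multiple-comparison machinery) are deliberately out
of scope — the tidy tables feed standard tools directly.

**IC50 fits** use the four-parameter logistic
`bottom + (top - bottom) / (1 + (dose/IC50)^hill)` minimized by
Levenberg–Marquardt least squares on log-dose. Initialization is a fixed
deterministic rule (extremes for top/bottom, the geometric mean of the
half-response-bracketing doses for IC50, Hill = 1), so fits are exactly
reproducible. Flat series (span < 0.1 normalized units) raise a
"no transition" condition instead of returning a meaningless IC50.

## Ratiometric indices

The **mito-QC mitophagy index** is defined in two ways in common use — a
count ratio (mCherry-only foci over mitochondrial objects) and a relative
mitolysosomal *area*. Area mode is the default here (the quantified figures
in this assay family use area) and count mode is retained; the foci count
is always reported. The mitochondrial mask is a threshold on mCherry, and
mitolysosomes are mask pixels whose ratio `mCherry / (GFP + 1)` exceeds a
fixed cut (default 2.0) in components of at least `min_focus_area`. A fixed
ratio cut was chosen over a data-driven (Otsu on log-ratio) default because
the degenerate but biologically meaningful fields — no mitophagy at all, or
complete conversion — have unimodal ratio distributions, and any data-driven
split invents a boundary there; Otsu remains available via
`ratio_threshold = "otsu"`. The `+1` denominator offset avoids division
blow-ups and costs gain invariance only in the strict sense; in practice
the classification margins are so wide that a 10x gain change moves the
index by less than 10^-6, which the tests assert.

**mtRosella** is a mean-intensity ratio (pH-stable DsRed over pH-sensitive
GFP) over a caller-supplied ROI. **TMRM/MitoTracker** is an area ratio; by
default one shared Otsu threshold computed on the MitoTracker (structural)
channel is applied to both channels, so a TMRM channel containing only
noise yields an empty mask and a ratio of 0 rather than a spurious split of
its noise floor. **JC-10** channel-to-role assignment (monomer vs
aggregate) is explicit caller configuration and never inferred from
emission wavelengths, because wavelength labeling conventions conflict
across sources. The **flow-cytometry flux** formula is
`((+Lys inhibitor) - (-Lys inhibitor)) / (-Lys inhibitor)`; negative values
are reported (flagged with a warning), not clamped.

## Physiological traces

`ocr_summary()` implements the respirometry rules exactly: basal = mean of
the last three points before FCCP; nonmitochondrial = mean after
rotenone/antimycin A (clamped at zero); mitochondrial basal = basal minus
nonmitochondrial, exact arithmetic. Two **maximal-OCR conventions** are in
genuine use — the maximum observed after FCCP, and the mean of the last
three points before R+AA — so both are implemented; the last-three rule is
the default and the output records which rule produced it. Traces whose
post-FCCP OCR never exceeds basal are flagged excluded ("did not respond to
FCCP") with the trace retained. Titration traces are normalized pointwise
to the control (carrier-only) chamber at nearest timestamps (tolerance:
half the control's median sampling interval) before IC50 fitting.

The **worm activity score** is the fraction of t0 worm pixels vacated at
t1: identical masks score 0, complete departure scores 1, and the stated
endpoints force this vacated-fraction reading over a symmetric-difference
variant (still available via `method = "symmetric"`). Scoring windows
within a video are aggregated by their mean. Alive/dead calls are inputs;
dead animals score 0.

## The synthetic-data module

Generators are seeded (bit-identical regeneration) and expose their
analytic expectations in the truth record so recovery tests never
hard-code numbers. Default conditions mirror the emulated acquisition:

* `make_larva_stack()`: 26 Z planes, a ~12,000 px^2 elliptical body (4:1
  aspect) of autofluorescence level 40 on dark level 5, 12 puncta of
  diameter 4 px at amplitude 200, Poisson shot noise plus Gaussian read
  noise with sd = amplitude/snr (default snr 20, i.e. read sd 10 — typical
  of a cooled confocal detector). Puncta are uniform discs by default so
  planted areas are exact pixel counts; puncta are placed in the body
  interior (margin radius + 10 px) because LC3 puncta sit in the trunk
  musculature, away from the skin edge — and because objects straddling
  the shrunk body mask are excluded by design, which a recovery oracle
  must not conflate with detection failure. The truth exposes
  `body_area_after_erosion()` (area − perimeter·r + πr², exact for a
  convex body when r is under the minimum curvature radius) so body-mask
  assertions can correct for the deliberate shrink.
* `make_mitoqc_field()` / `make_tmrm_field()`: a curvilinear network of
  thickened random walks at ~10% area density; contiguous blobs grown by
  in-mask BFS realize the planted mCherry-only (or TMRM-negative) area
  fraction *exactly*, which the truth records.
* `make_ocr_trace()` / `make_titration_traces()`: plateaus with injection
  steps; non-responders plateau at 75% of basal; titrations follow a known
  4PL truth.
* `make_worm_frames()`: the displaced mask is adjusted pixel-by-pixel so
  the vacated fraction is exactly `round(f * area) / area`.
* `make_screen()`: lognormal per-larva draws around group means implied by
  the planted effects; between-larva variation (CV 20%) is shared across
  the two phases of the same larva (it is imaged twice), with an 8%
  residual per acquisition. Doses follow the 10–250 uM ladder; NH4Cl
  doubles every group's mean; vehicle wells default to 3x the group size,
  as screens run many vehicle wells per plate.

What the generators do **not** emulate: optical point-spread functions,
depth attenuation, body autofluorescence texture, touching or overlapping
larvae, segmentation-relevant debris, plate spatial gradients, and drifting
acquisition focus. Passing recovery tests therefore demonstrates that the
analysis chain is correct and well-calibrated on images satisfying its
stated assumptions — not that the defaults are optimal for any particular
microscope's output, which is why every threshold is a config value.

## Numerical and degenerate-input choices

* Otsu thresholds are computed on max-normalized images, making them exact
  under global rescaling.
* Erosion can split a thin body mask; the largest component is kept so the
  single-connected-component invariant holds.
* The 4PL optimizer runs with tight tolerances (1e-12) and a fixed
  initialization; convergence failure is an error carrying the optimizer
  diagnostics, never a silent best-effort value.
* Vehicle means of zero make fold changes *absent with a reason*, not 0 or
  Inf; empty denominators across all ratio functions behave the same way.
* Problem sizes in the test-suite recovery studies — 50 stacks for puncta
  recovery, 200 Monte-Carlo screens for ranking, 100 traces/replicates for
  the OCR and IC50 checks — were chosen to give comfortable binomial
  resolution at the asserted rates while keeping a full test run in the
  minutes range on one core.
* The noisy IC50 recovery study uses a *replicated* titration design — 16
  log-spaced doses with 12 replicate responses per dose, i.e. two 96-well
  titration plates. This is a statistical necessity, not caution: at 5%
  response noise the free-4PL least-squares estimator itself has a ~16%
  median IC50 sampling error on 8 single responses (our optimizer reaches
  the same optima as `stats::nls(algorithm = "port")` on identical data),
  and only replication brings the estimator's sampling error under 5%.

## Known limitations

Toxicity and death calls are inputs, not computed. Cell segmentation for
per-cell ratiometrics is caller-supplied. 3D puncta segmentation is out of
scope (the analysis operates on 2D projections by design). The pilot
hit-calling threshold is conventional, not derived. Flow-cytometry gating
is upstream of this package; MFIs are consumed as given.
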