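---
title: "Cell-number normalization of extracellular flux data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-number normalization of extracellular flux data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pixflux)
```

## The problem

Extracellular flux analyzers report oxygen consumption (OCR, pmol/min) and
extracellular acidification (ECAR, mpH/min) per well of a 96-well plate.
For immortalized cell lines the number of cells per well is controlled well
enough that raw rates are comparable. For freshly isolated primary cells —
loosely attached, fragile, impossible to recount after plating — the actual
cell number per well can drift far from the seeding target, and that drift
propagates directly into the rates. Staining-based counting (Hoechst, DAPI)
fails for such cells: dye-efflux transporters defeat live stains, and the
washing required for fixed stains detaches the cells themselves.

`pixflux` implements the alternative: quantify cell material from a plain
brightfield image of each well taken *before* the run, calibrate that
quantity to cell number once, and express every metric per a fixed
reference cell number.

## The cell-pixel algorithm

For each well image the pipeline is:

1. **Grayscale conversion** to a canonical 0–255 intensity scale
   (3-channel inputs by unweighted channel mean; unit-scale and 16-bit
   inputs rescaled).
2. **Background estimation**: a normalized Gaussian low-pass filter with
   standard deviation `background_sigma`. Cells (a few pixels across at 4x
   magnification) vanish from the background estimate; the slowly varying
   illumination field remains.
3. **Correction and inversion** in one algebraic step,
   `clip(background − image, 0, 255)`. Brightfield cells are darker than
   their surroundings, so the difference is a white-objects-on-black image;
   subtracting then negating then clipping gives the identical result, and
   the equivalence is asserted in the test suite.
4. **Margin cropping** by `crop_fraction` per side (default 0.05,
   retaining the central 90% of each dimension) to remove the molded stops
   of the assay plate at the well rim.
5. **Counting**: every pixel with intensity strictly greater than
   `threshold` (default 1) is a *cell-pixel*.

The count is not a segmentation — overlapping or irregular cells are fine —
it is simply an area proxy for cell material, which is what normalization
needs.

### Parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| `background_sigma` | px | `min(h, w)/10` | must be large relative to a single cell (~5–10 px) so cells do not leak into the background; size-relative so the same setting works across magnifications |
| `crop_fraction` | — | 0.05 per side | rim artefacts sit on all four sides; 5% removes them without losing the probed area |
| `threshold` | intensity (0–255) | 1 | the inverted image is black (0) wherever the well is empty; any pixel meaningfully above zero is evidence of a cell |

The intensity scale on which a threshold of 1 is meaningful depends on the
grayscale conversion, which is why the conversion is pinned to 0–255 and
the threshold is an explicit parameter rather than a hard-coded rule.
Boundary handling for the Gaussian is edge replication: a constant image is
reproduced exactly (normalized kernel), and a linear gradient is its own
blur away from the border — both properties are tested against a direct
convolution written as an explicit double loop.

Images smaller than 16×16 px or containing non-finite values are rejected
outright rather than silently processed.

## Calibration

Wells seeded at a known density ladder (50,000–150,000 cells/well, four
densities, replicate wells, several subjects) give paired
(cell-pixels, seeded cells) points. `fit_calibration()` fits one pooled
second-order polynomial with **cells as the response**:

$$\widehat{\text{cells}} = a\,p^2 + b\,p + c, \qquad p = \text{cell-pixels}.$$

Fitting in this direction means converting new pixel values to cells is a
single polynomial evaluation; the alternative (fit pixels as a function of
cells, then invert by choosing a quadratic root) is deliberately not
implemented. The intercept is left unconstrained: forcing `c = 0` would be
physically appealing but the data near zero density are never observed, and
an unconstrained fit is what the pooled-curve workflow uses. The gentle
curvature absorbs the saturation that crowding produces at high density.

One *external* curve serves all plates. Image intensity differences between
plates do not change cell-pixel counts appreciably (the background
subtraction removes the illumination level), so no in-plate standard curve
is carried. Negative predictions are clipped to zero and flagged;
predictions outside the calibrated pixel range warn but do not fail,
because sparse wells legitimately fall below the ladder.

## Flux metrics

The extended mito stress test injects, in order: oligomycin (ATP-synthase
inhibitor, 1.5 µM), FCCP (uncoupler, 1 µM), rotenone + antimycin A
(complex I/III inhibitors, 1.25 + 2.5 µM), and 2-deoxyglucose (glycolysis
inhibitor, 50 mM). The default schedule has 12 measurement cycles of 3 min
with 2 min mixing: cycles 1–3 basal, injections before cycles 4, 7, 9
and 11. Twelve cycles cannot give three to every one of five phases; the
three-cycle allocation goes to the phases summarized by a tail mean (basal,
post-oligomycin), while phases summarized by an extremum (FCCP maximum,
inhibitor minima) work on two cycles. Both the cycle allocation and the
statistic per phase are configurable.

Per-phase levels use one of two statistics:

- `last_k_mean` (default `k = 3`): mean of the final *k* cycles of the
  phase, after the injection response has settled — used for basal OCR and
  ECAR and post-oligomycin ECAR;
- `extremum`: maximum OCR for the FCCP phase, minimum OCR for inhibitor
  phases, where inhibition is most complete.

Derived metrics follow the standard anatomy: ATP-linked = basal −
post-oligomycin; proton leak = post-oligomycin − non-mitochondrial;
spare respiratory capacity = maximal − basal; 2-DG-sensitive
non-mitochondrial = non-mito − post-2-DG. By construction
`basal = ATP-linked + proton leak + non-mito` — the identity is checked to
numerical precision on every synthetic trace. Basal OCR is reported raw
(not non-mito-corrected) because that is how basal figures are normally
read; a corrected variant (`basal_ocr_corrected`) is emitted alongside,
clearly labelled. No outlier rejection is applied within phases.

Wells whose basal OCR falls below the instrument detection limit
(20 pmol/min by convention, boundary inclusive: exactly 20 passes) are
flagged `qc_pass = FALSE`, retained in per-well outputs, and excluded from
every group statistic. Runs that stop early (e.g. no 2-DG injection) yield
`NA` for the affected metrics rather than zeros.

## Normalization and variation statistics

`normalize_metric()` re-expresses a rate at a reference cell number
(default 100,000, the usual plating target):
`value × reference / estimated`. Wells without an image-based estimate are
excluded from normalized summaries — they are never back-filled from
seeded counts, which is exactly the quantity the imaging is meant to
replace.

Within-subject variation is summarized by the standard score of each
technical-replicate well,

$$z_i = \frac{x_i - \bar{x}}{s}, \qquad s = \text{sample s.d. (} n-1 \text{)},$$

using the sample convention because subjects contribute only 4–10 wells.
Since signed z-scores average to zero by construction, the per-subject
summary reported is the mean of |z|; the raw signed scores are also
emitted. Between-subject variation is the coefficient of variation of the
per-subject means, `100 · sd / mean`, again with the sample s.d.

The energetic-phenotype view places each well at (OCR, ECAR) for the basal
state and (maximal OCR, post-oligomycin ECAR) for the stressed state, with
quadrant labels (energetic / aerobic / glycolytic / quiescent) relative to
configurable axis midpoints — midpoints default to the cohort means, since
absolute quadrant boundaries are assay-specific.

## What the synthetic generators emulate — and what they do not

`synth_well_image()` renders a smooth background (constant, gradient, or a
quadratic field), dark soft-edged disks (linear 1 px falloff, so
thresholding near disk edges is exercised), and additive Gaussian noise.
`synth_flux_plate()` builds cohorts where each well's true rate is a
per-subject per-cell rate times a log-normal cell count (log-normal because
counts are positive with a controllable CV, mimicking pipetting variation),
observed through per-cycle Gaussian noise. Default phase levels describe a
trace typical of primary intestinal epithelial cells: basal OCR 70 pmol/min
at the 100,000-cell target, a modest oligomycin response (hence a large
apparent proton leak), limited spare capacity, and a further OCR drop after
2-DG. `synth_calibration_data()` produces the pooled standard-curve design
(3 subjects × 4 densities × 4 wells, 5% multiplicative pixel noise).

These generators capture the *structure* real data has, not its optics or
biology: no phase-contrast halos, no debris or mucus, no focus drift, no
drug-response kinetics within a phase, and cell counts independent across
wells. Consequently, passing tests demonstrate that the algorithms are
correct and well-calibrated under their stated assumptions — not that the
pipeline is robust to every artefact a real plate can produce.

One structural consequence is worth spelling out. With cell counts sampled
independently per well at CV 25%, the seeding-induced component of
*between-subject* variation is only about 25%/√8 ≈ 9% for 8-well subjects;
normalization removes nearly all of it (simulated cohorts: CV ≈ 8.6% →
0.6%, reduced in 200/200 cohorts under constant per-cell rates). Real
cohorts gain more because pipetting bias is correlated within a subject —
each subject's wells are plated from one suspension — which inflates the
raw between-subject CV and is equally removed by per-cell normalization.
When a between-subject biological rate CV (the generator's cohort default
is 15%) is present, that component rightly survives normalization.

## Numerical choices

- Gaussian kernel truncated at `ceiling(3σ)` and renormalized to sum 1;
  constant preservation is exact to < 1e−9.
- The composed pipeline is bit-identical to its stepwise decomposition
  (same code path, asserted on random images).
- The decomposition identity of metrics is asserted at 1e−12 — exact up to
  floating-point associativity.
- Curve files store coefficients at 17 significant digits, so persistence
  round-trips losslessly.
- Degenerate inputs fail loudly: < 3 distinct calibration pixels, zero
  within-subject spread, empty basal phase, non-monotone trace time, and
  duplicate (well, cycle) rows are all named errors.
- All generators take an explicit seed and restore the caller's RNG state;
  fixed seeds give byte-identical CSV and PNG output.

Problem sizes in the test and acceptance runs — 50 random images up to
~512 px, 20 calibration replicates, 1,000 synthetic traces, 200 cohorts of
7 × 8 wells — were chosen as the smallest designs at which the checked
properties are statistically sharp.

## Known limitations

- The cell-pixel count is an area proxy: it cannot distinguish cells from
  similarly dark debris, and it saturates as cells overlap (the quadratic
  calibration absorbs mild saturation only).
- One external calibration curve assumes a stable imaging configuration;
  a changed objective, LED intensity or camera requires recalibration.
- The package consumes exported rates; sensor-level oxygen/pH
  deconvolution is out of scope.
- Descriptive statistics only: the package computes summaries, z-scores
  and CVs, not hypothesis tests.
- Normalization corrects for cell number, not for per-cell mitochondrial
  content; pairing with a mitochondrial-mass marker is a natural
  extension.
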