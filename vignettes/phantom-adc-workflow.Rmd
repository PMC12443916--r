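---
title: "Automated ADC quality assurance for diffusion phantoms"
author: "phantomADC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated ADC quality assurance for diffusion phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomADC)
```

## The measurement problem

Quantitative diffusion-weighted MRI reports the apparent diffusion
coefficient (ADC), and sites verify their scanners by imaging the
NIST/NCI/RSNA diffusion phantom: thirteen vials of aqueous
polyvinylpyrrolidone (PVP) at 0--50% concentration, each with a certified
reference ADC at 0 °C (an ice bath pins the temperature). A QA analysis
must sort the vendor-specific DICOM exports, find the vials, fit the
diffusion model, and summarise accuracy and precision — reproducibly and
without an operator drawing regions by hand. `phantomADC` implements that
pipeline end to end and ships a synthetic phantom image generator so every
stage can be validated without scanner data.

## Signal model and units

Inside a vial the trace-weighted signal follows a mono-exponential decay,

$$ s(b) = s_0 \, e^{-b \cdot \mathrm{ADC}}, $$

with $b$ in s/mm² and ADC in mm²/s. Estimation uses the linearised form

$$ \log s(b) = -b \cdot \mathrm{ADC} + \log s_0 $$

by ordinary, unweighted least squares — the standard practice for phantom
work at high SNR. With exactly two b-values the fit reduces to the closed
form $\mathrm{ADC} = \log(s_1/s_2)/(b_2 - b_1)$, which the implementation
uses verbatim in that case. No Rician-bias correction is applied: at the
SNR of phantom protocols the correction is negligible for ROI means, and
leaving the estimator plain keeps it comparable with published analyses.
$R^2$ is reported on the log-domain fit. Voxels with non-positive signal
cannot enter the log model; at the ROI-mean level they are an error
(a valid ROI mean is never $\le 0$), at the voxel level they are dropped
and counted, because single dark voxels are expected at high $b$.

Units are fixed once, in one module: ADC is carried in µm²/s
(1 µm²/s = 10⁻⁶ mm²/s; water at 0 °C ≈ 1100 µm²/s ≈ 1.1 µm²/ms).
Repeatability coefficients are reported in µm²/ms because the QIBA
diffusion profile states its tolerances in that unit.

## What the synthetic generator emulates

`simConfig()`/`simulatePhantom()` rasterise the 13-vial layout into axial
magnitude volumes:

* mono-exponential decay per vial from the template's reference ADC;
* optional spatial ADC bias in each vial's cylindrical frame — a quadratic
  term $c\,(h-h_0)^2$ along the bore and/or an exponential radial term
  $A\,(e^{r/\lambda}-1)$, the two shapes that gradient non-linearity
  imprints on phantom measurements;
* Rician magnitude noise $\left|(s+g_1) + i\,g_2\right|$ with
  $g_1,g_2 \sim N(0,\sigma)$, per-voxel independent;
* rigid in-plane offsets and rotations of the phantom;
* sessions (study dates a month apart) and repeats (acquisition times);
* classic DICOM output in four metadata dialects: the standard diffusion
  b-value tag, or Siemens/Philips/GE-style private tags, with the
  Philips-style private intensity scale exercised on write and read;
* optionally a scanner-style "inline" ADC map computed voxelwise from the
  noisy signals.

Default conditions are chosen as a realistic phantom protocol: b-values
{0, 200, 400, 800, 1000} s/mm², $s_0 = 1000$ with $\sigma = 10$ (SNR 100
at $b=0$), 1.25 mm in-plane resolution, 2 mm slices, a 128² matrix whose
160 mm field of view covers the phantom with margin for positioning
offsets of several millimetres.

The generator deliberately does **not** model EPI geometric distortion,
eddy currents, ghosting, coil sensitivity profiles, k-space effects or
partial-volume antialiasing (vials are rasterised by voxel-centre
membership so analytic oracles stay exact). Passing tests on synthetic
data therefore demonstrate the correctness of the analysis chain — not
robustness to distortions the generator never produces; for real EPI data
the shape-based detector is the robust choice precisely because those
distortions exist.

A note on the synthetic template: the shipped layout (centre vial, inner
ring of six at 28 mm, outer ring of six at 58 mm) staggers the outer-ring
angles non-uniformly so the 13-point constellation has no non-trivial
rotational symmetry. A perfectly periodic ring layout would make
geometry-only vial labelling ambiguous under rotation; physical phantoms
resolve this with asymmetric features, the synthetic template resolves it
in the layout itself. Its reference ADC values are round numbers and are
not certified data — real analyses must load the certificate values for
their phantom serial number from a config file.

## ROI detection

Two detectors place the 13 cylindrical ROIs.

**Shape-based** (`detectShape()`), the default for distorted EPI data:

1. threshold the lowest-b volume (Otsu, via EBImage) and keep axial slices
   with at least half the maximal foreground;
2. label connected components per slice, keep those with area within
   0.5–2 times the expected vial cross-section and circularity
   $4\pi A/P^2 \ge 0.6$;
3. average component centroids across slices into per-vial candidates;
4. match the 13-point template constellation to the candidates by
   exhaustive rotation search in 1° steps with centroid-aligned
   translation, minimising the summed nearest-neighbour distance; exact
   ties break toward the smallest rotation magnitude;
5. take each ROI centre in-plane from its matched centroid (transformed
   template point if unmatched) and axially from the centre of the
   contiguous slice range where the vial's mean signal stays at or above
   half its peak;
6. carve the cylinder of the requested policy.

Fewer than 10 matched vials is a detection failure (with a diagnostic
overlay when a path is configured); a mean residual above 3 mm only
warns. All thresholds (area band, circularity, rotation step, axial cut)
are options, not constants.

**Registration-based** (`detectRegistration()`), for longitudinal data
with stable geometry: normalised cross-correlation between the target and
a template image, optimised by Nelder–Mead over in-plane translation and
rotation plus axial translation, initialised at the intensity-centroid
difference. Since non-axial phantom orientations are out of scope, the
two out-of-plane rotations of a full 6-DOF rigid transform are not
searched; on axial phantom data they are degenerate with the in-plane
parameters for this nearly cylindrically symmetric object. Template ROIs
are mapped through the fitted transform with radius and height unchanged.
A final correlation below 0.5 is a detection failure.

Four ROI policies are built in: `manual_single_site` (3 central slices,
radius 5 mm), `manual_multi_centre` (single slice, radius 8 mm),
`optimal` (radius 5 mm, height 10 mm) and `whole_vial` (radius 12 mm,
height 32 mm). Slice-count policies snap the ROI centre to the middle of
the chosen slice run so cylindrical coordinates stay centred.

## Spatial bias analysis

Voxelwise fits in whole-vial ROIs give an ADC and cylindrical coordinates
$(r, h)$ per voxel. Bias is the estimate minus the reference; relative
bias subtracts each vial's central-core bias (core: $r \le 1$ mm,
$|h| \le 1$ mm), so by construction the core mean of relative bias is
zero. Voxels from all scans are pooled in the shared cylindrical frame
and binned — 0.5 mm radial bins, 1 mm height bins by default (binning is
not prescribed by the underlying methodology; these widths resolve the
bias shapes at the default voxel sizes) — with normal-approximation 95%
intervals ($1.96\,\mathrm{SD}/\sqrt{n}$).

The optimal ROI search returns the largest (radius, height) on its grids
(radius 1–12 mm by 0.5, height 2–32 mm by 2, spanning up to the
whole-vial policy) such that every constrained bin in **every** vial has
|mean relative bias| below the threshold (5 µm²/s by default). The
radial and height conditions are separable, so the maximal feasible pair
is unique; the joint worst-case across vials is used rather than
per-vial optima because a single ROI size must serve the whole phantom.
If a direction has no feasible grid value the smallest one is returned
with a warning. A useful analytic anchor: a pure quadratic axial bias
$c\,h^2$ crosses a threshold $T$ at full height $2\sqrt{T/c}$, which the
acceptance suite exercises with $c = 0.2$, $T = 5$ (height 10 mm).

## QA statistics

With the repeatability constant $2.77 = 1.96\sqrt{2}$:

* QIBA summary per vial: %bias $= 100(\bar{Y}-X)/X$; short-term
  $w\mathrm{SD} = \sqrt{\text{mean within-session variance}}$,
  $RC_{ST} = 2.77\,w\mathrm{SD}$, $CV_{ST} = 100\,w\mathrm{SD}/\bar{Y}$;
  long-term analogues over per-session means. Conformance compares
  |%bias| ≤ 3.60, $RC_{ST}$ ≤ 0.015 µm²/ms, $CV_{ST}$ ≤ 0.5%,
  $RC_{LT}$ ≤ 0.065 µm²/ms, $CV_{LT}$ ≤ 2.2%. Long-term metrics are
  reported absent with a single session.
* %RC per institute and vial: $100 \cdot 2.77 \cdot \mathrm{SD}/\text{mean}$
  over repeats; institutes without repeats are excluded and named.
  %RDC per vial across institutes' first repeats, needing at least three
  institutes. Summaries (median, range) aggregate per-vial values; the
  per-vial table is always returned so other aggregations can be derived.
* TOST equivalence: two one-sided paired Wilcoxon signed-rank tests at
  ±δ; the reported p is the larger of the two. Zeros are handled by the
  Pratt method (rank with zeros, drop them); the null distribution of the
  rank sum is computed exactly by dynamic programming over doubled
  midranks up to n = 25 and by a continuity-corrected normal
  approximation above, which keeps small-n results exact and everything
  deterministic. The minimal-tolerance search descends
  50…1, 0.9…0.1, 0.09…0.01 µm²/s and returns the smallest δ at which
  every vial is significantly equivalent (p < 0.05); no multiple-testing
  correction is applied, matching how per-vial equivalence stars are
  conventionally reported.

## DICOM handling

The reader/writer supports classic single-frame part-10 files in the
explicit-VR little-endian transfer syntax, with the geometry, rescale and
diffusion tags the pipeline needs. Stored values map to intensities as
`raw * slope + intercept`, divided by the vendor-private floating-point
scale when present. The b-value comes from the standard diffusion tag
when present, else from the vendor-private location (standard wins when
both exist). Enhanced multi-frame DICOM and compressed syntaxes raise an
explicit unsupported-format error rather than being skipped silently, so
a mixed export cannot lose series unnoticed. Unreadable files are
reported and skipped. Sessions default to the study date — one imaging
session per calendar day — with repeats ordered by acquisition time;
series sharing an acquisition time (a b-value sweep) form one repeat.
Inline ADC maps carry a configurable unit scale (default: stored unit =
1 µm²/s) because vendors differ in the stored unit.

Written pixel data are 16-bit with a per-series rescale slope, so a
DICOM round trip quantises intensities at about max/60000 — irrelevant
at protocol SNR, and the reason exactness-style checks run on in-memory
series while DICOM round-trip checks use a quantisation-aware tolerance.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles:
brute-force normal equations for the OLS fit, brute-force voxel
enumeration for cylinder carving and binning, the generator's ground
truth for detection and recovery, enumeration of all $2^n$ sign
assignments for the signed-rank distribution, pydicom as an independent
reader of generated files, and closed forms throughout. Simulated
studies in the tests use 128² × 20 volumes for detection and closure,
a 128² × 40 volume at 1 mm slices for the spatial analysis (fine axial
sampling resolves the 1 mm height bins), and 500 Monte-Carlo replicates
of a 12-session × 4-repeat design for the repeatability statistics —
sizes chosen to make the checks sharp while keeping the suite quick.

## Known limitations

Axial acquisitions only; classic explicit-VR little-endian DICOM only;
no gradient-non-linearity or EPI distortion correction (bias fields are
measured, not corrected); no temperature correction (the reference
values are taken at 0 °C); no IVIM/kurtosis/stretched-exponential
models; the PDF report is a rendering of the canonical CSVs, not a
styled document.
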