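---
title: "Quantifying marker expression in CAM xenograft tissue: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying marker expression in CAM xenograft tissue: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camquant)
```

## The problem

Human tumour tissue grown on the chicken chorioallantoic membrane (CAM) is a
fast, inexpensive xenograft model, but any excised tissue section contains a
mixture of cells: the human cells of interest, a dense membranous rim of
chicken cells where the section meets the CAM, and scattered chicken cells
infiltrating the human tissue. Fluorescence-based readouts — mean marker
intensity per cell, counts of marker-positive cells, double-positive
percentages — are only meaningful after the chicken cells have been
identified and excluded. `camquant` implements that workflow end to end:

1. **Nuclear segmentation** of the DAPI channel,
2. **Tissue classification** of each nucleus (human / peripheral chicken /
   infiltrating chicken) from three morphometric features,
3. **Per-cell fluorescence measurement** and positivity calling, with a
   morphology filter for fibrous stellate-cell markers,
4. **DAB immunohistochemistry scoring** by optical-density bins, and
5. **Relative expression** (ΔΔCq) with a dual fold-change/significance
   cut-off,

plus a **synthetic-scene generator** that renders CAM-like fields with known
ground truth, so that every stage is verifiable without access to original
tissue images.

## Nuclear segmentation

The DAPI channel is processed as: normalize 8-bit values to $[0,1]$;
estimate the background as the running minimum over a 50-px square window and
subtract it; saturate the result to its 5th and 95th intensity percentiles
(clip, then rescale so $P_5 \mapsto 0$, $P_{95} \mapsto 1$); keep pixels
**strictly above 0.4**; drop connected components below 10 px (debris);
route components **above 200 px** to watershed splitting. All constants sit
in `seg_config()` and in one defaults table used by the pipeline config.

Interpretation notes, where the procedure admits more than one reading:

* *Minimum filter.* A 50-px minimum filter applied directly would erase
  10–200-px nuclei, contradicting the downstream area thresholds, so it is
  implemented as background estimation followed by subtraction. The window is
  a 50-px-per-side square; both the size and the interpretation are
  configurable.
* *Area filter.* The debris rule is implemented as "remove components with
  area < 10 px, keep the rest": objects of 100–200 px must survive, since
  only objects above 200 px are routed to splitting. An optional
  `max_single_area` knob (off by default) can additionally drop large
  unsplittable objects.
* *Percentiles* use the linear-interpolation convention (R's default
  `type = 7`); a stated convention is needed because none is standard across
  imaging software.
* *Strict thresholds.* A pixel exactly at 0.4 is background, and a cell with
  exactly 5 px of marker overlap is negative; both inequalities are strict
  throughout.

### The tissue-density assumption

Percentile saturation followed by a *fixed* 0.4 threshold carries an implicit
assumption: the 95th intensity percentile must fall inside the nuclear-signal
range, i.e. **DAPI-positive pixels must exceed ~5% of the frame**. When
coverage is below 5%, $P_{95}$ lands inside the background distribution and
the rescale stretches background noise across $[0,1]$, putting a
scale-independent ~25–60% of background pixels above any fixed threshold —
the method degenerates regardless of how small the noise is. Tissue sections
imaged at 10× are nuclei-dense, so the assumption holds for the data the
procedure was designed for; the synthetic generator's defaults reproduce that
density (6–9% nuclear coverage), and the recovery analyses in the tests use
200 nuclei of 40–180 px on a 512×512 frame (~8% coverage) for the same
reason. This is the single most important applicability condition of the
pipeline: on sparse fields (isolated cells, low-magnification overviews) the
saturation step should be disabled or the threshold chosen adaptively.

### Watershed splitting

Components above 200 px are subdivided by a marker-controlled watershed:
seeds are local maxima of the component's Euclidean distance transform and
the flooding surface is the distance transform weighted multiplicatively by
the saturated DAPI signal (the product combines the two marker sources named
by the procedure). Two seed-suppression rules are applied:

* **Dynamics (h-maxima) tolerance**, default 1 distance unit: a candidate
  seed whose peak rises less than the tolerance above the level at which it
  meets a higher region is merged into that region. Discrete distance
  transforms of touching-nucleus unions carry genuine local maxima at the
  neck between the lobes and small plateau maxima along ridges; without a
  depth criterion these produce spurious fragments. The default matches the
  common default of flooding implementations (e.g. `EBImage::watershed`,
  which the tests use as an independent cross-check).
* **Spatial merge**, default 3 px: surviving seeds closer than 3 px are
  merged (single linkage), suppressing plateau duplicates.

Flooding is implemented as union-find over pixels visited in decreasing
surface order, with ties broken by pixel index, so results are deterministic.
Splitting never adds or removes foreground pixels, and a component with a
single surviving seed is kept whole — convex ~250-px ellipses must not
fragment, and the tests assert they do not.

## Nucleus classification

Three features per nucleus: **area** (pixel count), **eccentricity** (of the
ellipse with identical second central moments; 0 = circle), and **k-3
density** — the mean Euclidean centroid distance to the 3 nearest other
nuclei. Human nuclei are large and round; chicken nuclei (erythrocyte-like)
are small and elongated; the CAM rim is densely packed (low k-3) while
infiltrating chicken cells sit sparsely in the human tissue (high k-3). With
fewer than 4 nuclei the k-3 density is reported missing, and classification
falls back to the remaining features with a warning.

The classifier is linear: features are z-scored and a pooled-covariance
linear discriminant is fitted (`MASS::lda` behind `train_classifier()`); the
decision rule is the argmax of one affine score per class, and exactly those
weights are serialized to versioned JSON, so a reloaded model reproduces
predictions bit-for-bit. Standardization is this package's choice — area
(~10²) and eccentricity (~1) are on incommensurate scales. Three classes are
used, matching the enumerated tissue categories; whether the original
classifier was truly 3-class or binary with an edge heuristic is not
decidable from the procedure's description, and the 3-class reading is the
more expressive one.

Two training entry points exist:

* `train_classifier()` on any labeled feature table (the CSV interface uses
  columns `label, area_px, eccentricity, k3_density_px, class`);
* `train_classifier_on_scenes()` mirrors the study-style workflow of
  pretraining on curated images from the same dataset: labeled synthetic
  scenes are segmented and their measured features (not the generator's
  targets) form the training table. Because measured feature distributions
  depend on the scene conditions (e.g. cell spacing drives k-3), models used
  for exact-recovery analyses are trained on scenes drawn from the same
  conditions as the scenes they classify.
* `default_classifier()` ships as a convenience: an LDA fit on the synthetic
  "separable" preset (`sample_separable_features()`), cached per session.
  For real data, train on curated labeled nuclei instead.

`exclude_cam()` implements the human-analysis view: peripheral-chicken
records are excluded outright; infiltrating-chicken records remain in the
record set (they are reportable) but both chicken classes are excluded from
all human-cell metrics in `summarize_slide()`.

## Per-cell fluorescence

Cytoplasmic territories are grown from the nuclei with a seeded propagation
(`EBImage::propagate` on a flat landscape — the standard cell-profiling
algorithm), restricted to pixels within `expansion_radius` (default 10 px,
the procedure gives no bound) of the nearest nucleus. This realizes the
nearest-nucleus partition up to ±1 px along exactly equidistant boundaries,
where the propagation order, not the lower label id, breaks ties; the tests
assert the perpendicular-bisector property away from the tie zone.

Marker channels are prepared like the DAPI channel but **without** percentile
saturation (normalize, subtract background, threshold strictly above 0.4).
Per cell and marker the package reports nuclear MFI, cytoplasmic MFI, and a
combined MFI. "Averaged together" is ambiguous between the mean of the two
region means and a pooled-pixel mean; the region-means rule is the default
(the two regions are named as separately measured, then averaged) and the
pooled mean is available via `combine = "pooled"`. Slide-level means are
reported over all cells of the class and over positive cells only, since the
procedure does not say which enters the headline figures.

A cell is positive for a marker iff its region overlaps the prepared marker
mask by **strictly more than 5 px**. The overlap region defaults to the full
cell (nucleus + cytoplasm; `positivity_region = "nuclear"` restricts it).
For fibrous markers (ACTA-2 in the study), the mask is first passed through
the **elongation filter**: keep components with area > 20 px AND
perimeter/area > 0.5. The ratio threshold is estimator-dependent, so the
estimator is pinned: the default is the 4-connected boundary-step count (a
$w\times h$ rectangle scores exactly $2(w+h)$, so a 2×30 fibre has ratio
64/60 ≈ 1.07 while a radius-10 disk scores 84/317 ≈ 0.26); a Crofton-style
estimator is available as an alternative and is also below 0.5 on disks.
Double-positive percentages use the first marker of the pair as the
denominator (the figure-caption reading: "cells positive for ACTA-2 and
MMP2" among ACTA-2⁺ cells); empty denominators give `NA`, never 0.

## IHC scoring

The DAB module is a deliberately small scoring rule, not a re-creation of a
full positive-cell-detection pipeline (no background radius, sigma, or cell
expansion — those belong to the published tool the study used). From an RGB
image, the optical-density sum is
$\mathrm{OD} = \sum_{c \in \{R,G,B\}} -\log_{10}(\max(I_c, 1)/255)$ (pure
white → 0; zeros floored before the log). Cells — any label map from this
package's segmentation/assignment machinery — are positive when their mean
OD is at least 0.1 and are binned by left-closed intervals at the printed cut
points: $[0.2, 0.4) \to$ 1+, $[0.4, 0.6) \to$ 2+, $[0.6, \infty) \to$ 3+.
The boundary rule (0.4 is 2+) is this package's documented choice; means are
compared with a $10^{-9}$ tolerance so that averaging noise cannot flip a
cell across a cut it sits on exactly. Whether the 0.1 threshold applies to
the mean or the maximum OD is not stated; the mean is used.

## Relative expression

ΔCq per sample and target gene is the target's replicate-mean Cq minus the
arithmetic mean of the two housekeeping genes' replicate-mean Cqs
(equivalent to geometric-mean normalization of quantities). ΔΔCq is the
treated-group mean minus the untreated-control mean, and fold change is
$E^{-\Delta\Delta Cq}$ with amplification efficiency $E = 2$ — the classic
assumption; $E$ is a parameter since the study's vendor software does not
state efficiencies. The p-value is a two-sided Welch t-test on per-sample
ΔCq values (the cut-off logic is agnostic to the p's source; singleton or
zero-variance groups report `NA`). The dual cut-off flags a gene iff
$|\log_2 \mathrm{fold}| > 1$ AND $p < 0.05$, both strict; the fold criterion
is applied symmetrically to down-regulation, since expression displays show
both directions around fold 1. A fold change above 2 with $p = 0.061$ is
not flagged. No multiple-testing correction is applied, matching the
original analysis; users testing many genes should consider one.

## The synthetic-scene generator

`generate_scene()` renders, at pixel resolution with 8-bit round-half-up
quantization:

* **Human nuclei**: filled ellipses with area uniform in 80–180 px²,
  eccentricity 0.2–0.5, orientation uniform in $[0, \pi)$, placed by random
  sequential adsorption in the interior. When marker channels are present,
  an extra centre clearance (default 28 px) keeps every cell's marker
  footprint inside its own cytoplasmic territory, so positivity and MFI
  recovery are exact by construction.
* **Touching pairs** (optional): near-equal ellipse pairs (area ratio
  0.9–1.1, summed area ≥ 280 px²) at centre offset $0.9(r_1+r_2)$ — the
  union exceeds the 200-px splitting threshold and its distance transform is
  clearly bimodal, which is what the splitting stage is specified to handle.
* **CAM rim**: elongated nuclei (25–50 px², eccentricity 0.8–0.95) on a
  jittered annular lattice inside a `rim_width` border band, oriented along
  the border — a dense membranous rim that gives the k-3 feature its signal.
* **Infiltrating chicken nuclei**: same morphology, sparse in the interior.
* **Markers**: `cytoplasmic_ring` paints the cell body (nucleus dilated by
  12 px, covering the default 10-px cytoplasm), `elongated_fibre` paints a
  2–3-px-wide, ~31-px-long axis-aligned bar through the cell — aspect ratio
  above 5, so it passes the elongation filter by construction.
* **Noise**: additive Gaussian (default sd 0.05) clipped to $[0,1]$ before
  quantization. DAPI nuclei render at 0.9 on a 0.1 background (the nuclear
  intensity is a generator parameter; it has no counterpart in the imaging
  procedure, which starts from recorded images).

Default counts (45 human, 300 rim, 8 infiltrating on 512×512 with a 40-px
rim) give 6–9% nuclear coverage — the tissue-density regime discussed above.
Identical parameters (including the seed) give bit-identical scenes; impossible
placement requests fail with an error naming the offending count.

What the generator does **not** emulate: point-spread blur, vignetting,
autofluorescence and chemical-bleaching residues, intensity gradients,
out-of-focus nuclei, nuclear texture, or overlapping cytoplasm between
neighbouring cells. Passing the recovery analyses therefore demonstrates the
correctness of the measurement logic under the stated geometry and noise
model — not segmentation robustness on real tissue.

## Problem sizes and determinism

The test suite and the verification script use 512×512 scenes
(200–353 nuclei) for recovery analyses, a 1024×1024 scene (~800 nuclei) for
the runtime check, 50 touching pairs for the splitting analysis, and
500-train/500-test feature draws for classifier accuracy; on one CPU core the
whole suite runs in well under a minute. Every random quantity flows from a
single integer seed (the generator restores the caller's RNG state), the
watershed and propagation stages are deterministic, and two pipeline runs
with the same config and inputs produce byte-identical CSVs.

## Known limitations

* The density assumption above: sub-5% DAPI coverage breaks the fixed-0.4
  threshold after percentile saturation.
* The shipped default classifier is trained on synthetic features; real
  slides need a model trained on curated labeled nuclei
  (`train-classifier` CLI subcommand or `train_classifier()`).
* Cytoplasm tie-breaking follows propagation order rather than a documented
  label-id rule (±1 px effect at exactly equidistant boundaries).
* The elongation filter's ratio is resolution-dependent (perimeter/area has
  units of 1/length); the 0.5 cut is tied to the study's pixel scale, which
  is not reported in physical units — all geometry here is pixel-denominated.
* IHC scoring reuses this package's segmentation; scores are comparable
  within analyses run by this package, not with tools using different cell
  detection.
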