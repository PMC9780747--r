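---
title: "Methods: staging seminiferous tubules from tiled detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staging seminiferous tubules from tiled detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(semistage)
```

## The problem

A mouse testis cross-section contains 100–200 seminiferous tubule
profiles. Each profile sits at one stage of the seminiferous epithelial
cycle, recognizable from its cellular composition: which of the nine
epithelial cell types (Sertoli cells, spermatogonia, pre-pachytene and
pachytene spermatocytes, secondary spermatocytes, meiotic metaphase
plates, round spermatids, early and late elongating spermatids) are
present and where they sit radially. `semistage` takes per-tile object
detections — from any backend honoring a small contract — and produces
staged tubules, per-cell classifications, crosstab reports, and
marker-expression profiles for the whole slide.

## Coordinate and geometry conventions

All coordinates are 0-based with x = column and y = row; boxes are
half-open (`[x0, x1) × [y0, y1)`), so a box's pixel count is exactly
`(x1−x0)(y1−y0)`. Every overlap ratio (box or mask) is a Jaccard index on
the discrete pixel lattice, which makes box IOU and mask IOU mutually
consistent — a property the test suite checks by enumeration. Rasterized
ellipses include a pixel when its centre satisfies the ellipse inequality
with `≤`; this makes small-region behavior deterministic and testable.
Quarter-turn rotation is defined by the pixel map `(x, y) → (y, s−1−x)`,
and box rotation is verified against rotating a rasterized mask.

## Pipeline stages and their parameters

* **Tiling** (`slice_slide`): tile side 1024 px, second lattice shifted by
  512 px in both axes. Trailing partial tiles are dropped rather than
  padded: padding would fabricate dark tissue, and the shifted lattice
  recovers most border loss. An optional foreground filter (fraction of
  pixels above an intensity floor, default floor 20/255, filter off by
  default) approximates the exclusion of empty-glass tiles; there is no
  principled universal cutoff for "glass versus tissue", so it is an
  explicit configuration knob rather than a fixed rule.
* **Detection contract**: backends return full per-class confidence
  vectors; score suppression (0.5 for cells, 0.3 for tubule fragments)
  happens in the contract, not in backends, so backends are comparable. If
  a backend only produces a top-1 score, the adapter convention is to
  spread the remaining mass uniformly — the product stage vote needs
  all-class values.
* **Rotation ensemble** (`merge_rotation_ensemble`): detections from the
  four rotations are pooled, sorted by descending confidence (ties: order
  of arrival, i.e. lower rotation index first), and kept greedily unless
  IOU with a kept detection exceeds 0.5 — strictly: an overlap of exactly
  0.5 survives.
* **Cross-tile merge** (`merge_cross_tile`): single-linkage clusters at
  IOU ≥ 0.4 over box centres binned on a spatial grid. Per cluster the
  class score is the sum of member confidence vectors; the merged box is
  the confidence-weighted mean of member boxes (the union or the
  top-confidence box would be defensible alternatives; the weighted mean
  is smooth and symmetric, and the choice is isolated in one function).
  The merged confidence vector is the vote vector normalized to sum 1 so
  detection invariants (simplex-bounded confidence) hold after merging;
  the argmax and runner-up — retained as the second-best prediction — are
  unaffected by the normalization.
* **Tubule assembly** (`group_fragments_to_tubules`): fragments are joined
  when their mask intersection reaches 10 % of the smaller fragment's
  area; connected components become tubules. The 10 % threshold is a
  design choice: low enough to chain fragments offset by half a tile,
  high enough to ignore sliver contacts. Tubule ids follow scanline order
  of union-mask centroids, so output is deterministic.
* **Stage vote** (`vote_tubule_stage`): `w_i(c) = conf_i(c) · area_i /
  area(union)`, `S(c) = Π_i w_i(c)`, argmax over the five stage classes,
  ties broken by stage order. The product is computed in log space with
  each factor floored at `1e-6`: without the floor a single
  zero-confidence fragment would veto a stage outright, which a
  multiplicative vote should not allow. The log-space form equals the
  direct product to `1e-9` relative tolerance (tested on random fixtures).
* **Stage-XII rules** (`apply_stage12_rules`): stage XII is defined by
  meiotic figures, so (1) a XII-voted tubule with no `m2m`/`Spc-sec` cell
  is restaged I-V (stage XII and early stage I tubules are otherwise easy
  to confound), and (2) an `m2m`/`Spc-sec` cell in a non-XII tubule takes
  its second-best class or is removed. The rules run once, in that order:
  letting rule 2 re-trigger rule 1 (a XII tubule emptied of its meiotic
  figures by relabeling) could cascade, so a single ordered pass is used
  and documented. Rule 2 applies only to cells assigned to a tubule;
  interstitial cells are untouched.
* **Curation**: instead of a GUI, `exclude_tubules` drops listed tubule
  ids from all reports; the overlay PNG supports the visual review.

## The oracle backend and its noise model

The oracle backend replays ground-truth annotations as detections, which
pins down every pipeline stage's correctness: with zero noise the pipeline
must reproduce the generator's truth exactly (100 % stage accuracy,
crosstab identity), and the test suite asserts exactly that.

Noise realization has one important subtlety: cell-level noise (drops,
label flips, box jitter) is drawn once per ground-truth object at backend
construction, not per tile or rotation. Otherwise a cell seen by four
rotations and up to two overlapping tiles would get eight independent
chances to survive a drop, and a drop probability `d` would not translate
into sensitivity `1 − d`. Fragment stage-label flips are instead drawn per
(tubule, tile) pair — fragments are the units the stage vote consumes, so
per-fragment errors are what the vote must be robust to; this produces a
smooth, monotone degradation of stage accuracy as the flip probability
rises, which the acceptance suite measures over ten seeds. Label flips
sample uniformly from the other classes present in the annotation set
(a detector confuses classes that exist in its world).

## The baseline backend

A weights-free classical detector demonstrates the contract end to end:
intensity threshold → connected components (EBImage's labeling) → area
filter → nearest-centroid classification in (area, mean intensity,
eccentricity) space, with confidence the normalized inverse centroid
distance. Its per-class centroids are computed from the synthetic
renderer's parameters (`render_feature_centroids`), which is the point:
the baseline is guaranteed learnable on the synthetic material and
exercises the same code paths a neural backend would. Its tubule head
finds tissue blobs at a low threshold after smoothing and scores stages by
a composition heuristic over the cell classes detected inside each blob.

## The synthetic slide generator

The generator emulates what staging logic needs from DAPI histology and
nothing more:

* **Geometry**: non-overlapping elliptical tubules (semi-major axis
  130–190 px, axis ratio 0.78–1, ≥ 25 px apart) placed by dart throwing
  with an attempt budget; cells in radial layers (basal spermatogonia and
  Sertoli cells, then spermatocytes, then round spermatids, then the most
  luminal spermatids), late elongating spermatids bundled in stages I–V.
  Tubules are placed only where the default tile lattice provides
  overlapping coverage (inside a single tile or inside the
  shifted-lattice region) — mirroring real whole-testis scans, where
  tissue sits in the slide interior and border profiles are curated away —
  so that fragment grouping is well-posed.
* **Composition** (`stage_composition_rules`): per stage, required /
  allowed / forbidden classes with count ranges scaled by tubule area.
  Stage XII requires at least one metaphase plate or secondary
  spermatocyte; stages IX and X–XI forbid round spermatids; I–V and
  VI–VIII require them; Sertoli cells are present at every stage. The
  ranges themselves (roughly 8–12 Sertoli cells, 12–18 pachytene
  spermatocytes, 20–30 spermatids per reference tubule) are plausible
  orders of magnitude for a 5 µm section, chosen once; no per-class
  nuclear statistics are published for the real material, so the rendering
  parameters are synthetic and labeled as such.
* **Appearance**: per-class nuclear semi-axes, mean intensity, axis ratio
  and texture amplitude, plus Gaussian noise (σ = 2.5 on a 0–255 scale).
  Classes are separated by a comfortable margin in (area, intensity,
  eccentricity) so the baseline detector can learn them. This is *not*
  photorealistic DAPI texture: chromatin patterns, intensity gradients,
  touching nuclei, sectioning artifacts and transitional tubules (off by
  default; a `transitional_prob` flag mixes adjacent-stage compositions)
  are all absent or simplified. Passing tests therefore certify the
  pipeline logic, not detector performance on real slides.
* **Markers**: each marker rule names positive classes, positive stages
  and a contrast; channels render positive nuclei bright (default 180)
  over a dim background (6). The defaults emulate a pan-Sertoli marker, a
  stage-dependent Sertoli marker (early-to-mid stages only), and a
  pan-spermatogonial marker.
* **Knockouts**: `miwi` mode removes all elongating spermatids (arrest at
  the round-spermatid stage) while keeping stage labels; `spef2` mode only
  distorts elongating-spermatid rendering (wider, less eccentric), leaving
  ground truth identical to wild type.

Everything is deterministic given the seed; the same seed reproduces the
slide bit for bit.

## Positivity rule and profiling

A cell's region is the axis-aligned oval inscribed in its box. The cell is
positive for a marker when the region mean exceeds the user-set threshold
T **and** at least 65 % of region pixels exceed T/2 (the second clause
suppresses cells whose mean is carried by a bright speck). "Above" is read
as strict `>` and the fraction as `≥ 0.65`; both readings are documented
and overridable in `positivity_rule`. Luminosity is measured on raw
channel intensities — no normalization or flat-field correction — and
threshold selection is deliberately manual (`marker_intensity_report`
assists). Oval regions leak neighboring signal when nuclei are close;
profile tolerances in the tests (≥ 0.95 positive for truly expressing
(class, stage) pairs, ≤ 0.05 elsewhere) absorb that leakage.

## Evaluation module choices

Matching is greedy by descending confidence at a fixed IOU threshold
(default 0.5) and class-agnostic by default, with classification scored
afterwards — that is what makes a confusion matrix possible; a
class-aware variant is available by flag, and COCO-style AP always matches
within class. Ratios with empty denominators are reported `NA`
(undefined), never silently 0, and macro averages run over defined classes
only. AP uses the 101-point interpolated precision-recall curve and is
reported on the 0–100 scale. The four pixel-level metrics (pixel accuracy,
mean accuracy, mean IU, frequency-weighted IU) follow the standard
count-matrix formulas, with means over classes present in the truth.
Staging agreement takes an explicit set of reconciled tubule ids
(adjudicated borderline cases, e.g. stage V/VI boundaries) rather than
guessing how borderline cases were reassigned.

## Problem sizes and numerical notes

The shipped test and acceptance runs use synthetic slides of 8 tubules
(2048² px) for unit and degradation work and 30 tubules (4096² px) for the
end-to-end exactness check — large enough to exercise multi-tile tubules,
half-overlap duplication, and all five stages, while a full suite completes
in minutes on one CPU. The degradation suite runs label-flip levels 0,
0.1, 0.2, 0.3 over ten seeds and asserts a monotone (within a 0.05
sampling-error slack) decline in mean stage accuracy from exactly 1.0 at
zero noise, and detection sensitivity within a binomial confidence bound
of `1 − d` under drop probability `d = 0.2`.

Degenerate inputs are errors, not silent defaults: zero-area boxes, empty
masks, empty tubules in the stage vote, out-of-bounds regions in
positivity scoring, and mismatched label-image shapes all raise with a
named cause. Ties are broken deterministically everywhere (confidence
ties by order of arrival; stage ties by stage order; shared tubule
boundary pixels by lower tubule id).

## Known limitations

* Synthetic appearance does not imitate real DAPI texture; conclusions
  about detector accuracy on real tissue require real annotations.
* The pipeline emits exactly one stage per tubule; transitional profiles
  (two stages in one cross-section) are represented only through the
  optional generator flag, not modeled in the output.
* Whole-slide inputs are plain TIFF/PNG; pyramidal scanner formats are out
  of scope, as is sub-pixel registration of marker channels.
* The cell detector contract works on boxes, not instance masks — cell
  IOU is box IOU throughout.
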