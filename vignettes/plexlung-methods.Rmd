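---
title: "Single-cell phenotyping of multiplexed mouse lung images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell phenotyping of multiplexed mouse lung images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plexlung reimplements, as tested and reusable R code, a complete single-cell
analysis of cyclic (MILAN-style) multiplex immunofluorescence of mouse lung:
normal tissue and the Bleomycin fibrosis model. The measurement chain it
models is: one FFPE section is stained and stripped over 11 rounds (up to 3
fluor channels plus DAPI per round, 24 primary antibodies in total), every
round is scanned, all rounds are aligned onto a common frame, nuclei are
segmented from DAPI, each nucleus plus a thin cytoplasmic rim becomes one
"pseudo-cell", mean marker intensities per pseudo-cell feed a
PhenoGraph-style clustering, clusters are assigned cell types from a marker
signature table, and compositions and per-type transporter (P-gP)
intensities are quantified across a treatment time course. Because no raw
mouse images are publicly deposited, every stage is exercised against a
synthetic image generator with per-cell ground truth.

This vignette records the models, parameter choices and their rationale, and
what the synthetic benchmark does and does not demonstrate.

## The marker panel and signature matrix

The packaged panel (`default_panel()`) is the 24-antibody, 11-round design:
stromal (COLL1, VIM, FGF10), vascular/mural (vWF, aSMA, SM22, DESM),
epithelial (PanCK, MUC5b), alveolar type 1 (AQP5, PDPN, RAGE, HOP), alveolar
type 2 (SPD, NKX2-1, ABCA3), hematopoietic (CD3, PAX5, CD206, OPN, MPO), and
three measured-only markers (MMP7, P-gP, BCRP). 23 of the 24 markers form
the classification feature set; BCRP is carried as measured-only because it
contributes to no phenotype definition. P-gP stays in the clustering
features — it is constitutively expressed at type-dependent levels and so
carries neighborhood information — but is lineage-neutral (`ANY` in every
signature row), so it never scores for or against a type.

The extracted staining design does not state each marker's fluor channel;
the packaged channel assignments are reconstructed from the
secondary-antibody list (AF488 = FITC, rhodamine = TRITC, AF647 = far red)
under the constraint of one fluor per marker per round. Nothing quantitative
depends on the specific assignment except that autofluorescence is
subtracted from FITC and TRITC only.

`build_signature_matrix()` turns the per-marker target lists into a
type x marker matrix over `POS`/`NEG`/`ANY`. The transitional AT type —
cells co-expressing AT1 and AT2 markers — is `POS` for both alveolar marker
sets; its defining rule during assignment is co-positivity of at least one
AT1-restricted and one AT2-restricted marker.

## The synthetic generator

`generate_section()` renders a full acquisition; `simulate_cell_table()`
draws the same tissue model directly as a feature table (see *Scale
choices*). The generator's defaults are the study conditions:

* **Density and geometry.** 6,029 cells per 2 mm core (the study's average
  per-core yield) at 0.92 um/px; nucleus radius 3.5 +/- 0.5 um. Vasculature
  and myofibroblast/SMC nuclei lie along random Bezier "vessels", bronchial
  cells on circular airway rims, stromal cells partly perivascular with
  3:1-elongated nuclei (which deliberately reproduces the known weakness of
  nucleus-seeded segmentation for elongated cells); everything else is
  uniform. A configurable fraction (5%) of nuclei is planted touching
  another nucleus to exercise watershed splitting and the hybrid-signature
  artifact path.
* **Composition.** The published normal-lung percentages, renormalized to
  sum to 1 (the printed values total 95.7): AT1 23.0%, AT2 14.6%,
  transitional AT 33.4%, bronchial/goblet 7.3%, vasculature 3.1%,
  myofibroblast/SMC 2.1%, stromal 0.7%, T 7.3%, B 3.1%, macrophage 4.2%,
  neutrophil 1.0%.
* **Intensity model.** Truncated normal per (type, marker) on 0-255:
  positives 140 +/- 45, transitional AT at 0.7x, dark background ~8, DAPI
  190 +/- 25, P-gP baseline 60 for every type scaled by the treatment
  multipliers. The positive-over-background contrast (about 2.6 noise SDs
  per marker) was chosen once as representative of usable 8-bit
  immunofluorescence; with 2-4 positive markers per type it leaves types
  separable in marker space while keeping populations of a few tens of
  cells near the resolution limit of k = 30 graph clustering.
* **Autofluorescence.** Constant plus low-frequency value-noise texture,
  FITC (25 + 15) stronger than TRITC (15 + 10), zero in far red; a blank
  round 0 records it for subtraction, matching a protocol that subtracts AF
  from FITC/TRITC only.
* **Misalignment.** Per-round rigid motion, uniform within +/-10 px and
  +/-2 degrees — the magnitude of slide re-mounting between scan rounds,
  and exactly the model class the registration estimates.
* **Spillover.** In the table path, each cell's observed profile mixes in a
  Beta(1.2, 8.8) fraction (mean 12%; Beta(4, 6) for touching pairs) of its
  nearest neighbor's profile, emulating the pseudo-cell signal leakage that
  nucleus-seeded segmentation cannot avoid. In the image path the same
  effect arises physically from ROI overlap.
* **Treatment presets.** `treatment_preset()` encodes the published course
  qualitatively: transient AT1 dip, progressive AT2 + transitional decline
  to day 21, monotone stromal rise with a late myofibroblast/SMC increase,
  near-control day 28; P-gP multipliers above 1 after treatment for every
  type except bronchial/goblet, with stromal onset delayed past day 7.
  Exact per-day fractions are the package's own interpolation of those
  published directions, which are reported graphically rather than as a
  machine-readable table.
* **Per-mouse variation.** Cohort simulation jitters each mouse's
  composition with a Dirichlet of precision 60, which reproduces the
  published across-mouse SD scale (about 5-10 percentage points for the
  major types). Single-core runs use the preset composition exactly
  (multinomial sampling only), because the benchmark compares one core
  against the published group means.

What passing tests show — and what they do not: recovery on this generator
demonstrates that the pipeline's stages are correct and internally
consistent at realistic signal-to-noise, density and misalignment; it does
not demonstrate performance on real slides, where autofluorescence is
structured, staining failures and section artifacts occur, intensity
distributions are heavy-tailed, and cell-type marker profiles are far less
textbook than any signature table.

## Registration and autofluorescence subtraction

Rigid alignment (rotation + translation, the stated model of the original
workflow) is estimated per round from DAPI against the round-1 DAPI:
a coarse rotation grid (+/-5 degrees, 1-degree steps, at ~256 px scale)
scored by the phase-correlation peak, parabolic refinement of a 0.1-degree
grid at ~512 px scale, then sub-pixel phase-correlation translation at up to
~1200 px scale. FFT inputs are center-cropped to 5-smooth sizes. On
synthetic stacks the worst-case recovery error is about 0.02 degrees and
0.15 px — comfortably inside the 0.1 degree / 0.5 px contract the tests
enforce. Resampling is bilinear with round-half-up back to 8 bit; the
correction transform convention is documented in `estimate_rigid()`
(an image shifted by (+5, -3) yields translation (-5, +3)).

AF subtraction is pixel-wise `max(marker - blank, 0)` on the registered
blank round, FITC and TRITC channels only.

## Segmentation and features

`segment_nuclei()` follows the classical recipe: isodata global threshold
(the "default" automatic threshold of interactive tools; Otsu and fixed
cutoffs are exposed), Euclidean distance transform, watershed with h-minima
tolerance 1 to split touching nuclei, connected components, and an area
filter (min 20 px^2; max 10x the median object area — the original tool's
particle-size bounds are unpublished). `expand_to_cells()` grows each
nucleus by a 2 px ring (about 1.8 um at the default scale — the cytoplasmic
rim choice is a declared default, the original expansion being unstated)
by geodesic Voronoi propagation, so neighboring cells share boundaries and
never overlap. Features are the mean of each marker over the expanded ROI,
with nuclear centroids; rescaled values are `raw / 255` exactly, and
clustering runs on the linear 0-1 scale (no z-scoring or arcsinh — only a
linear rescale is stated by the source workflow).

## Clustering and classification

`phenocluster()` implements the PhenoGraph recipe with k = 30 (the
published setting): exact Euclidean kNN (RANN, the same backend the
reference R implementation uses), Jaccard re-weighting over neighborhoods
including the cell itself, Louvain modularity communities (igraph, seeded
node order; labels relabeled by decreasing size). No PCA pre-reduction: 23
features do not need it. t-SNE/UMAP embeddings are visualization-only.

Cluster-to-type assignment automates what was originally manual heatmap
reading, in three steps:

1. **Positivity calling.** Default: per marker, 1-D 2-means over the
   cluster means; clusters above the midpoint of the two centers are
   positive, unless the centers are closer than 0.1 (no positive population
   exists). A z-score rule (mean + z SD across clusters, z = 1) and a fixed
   cutoff are available as `method = "zscore"` / `"fixed"`. The midpoint
   rule is the default because the z-score rule breaks structurally on this
   panel: pan-epithelial markers are positive in most clusters (so mean +
   SD exceeds every cluster) and transitional AT sits at 0.7x of full
   positives (so the cutoff lands above it, silently discarding a third of
   the tissue as "null phenotype"). The 2-means midpoint handles both while
   reproducing the same calls on well-separated cases.
2. **Artifact rules.** A cluster whose positive markers span two or more
   mutually exclusive lineage compartments (epithelial / hematopoietic /
   mesenchymal / vascular; packaged as `lineage_groups()`) is discarded as
   a hybrid-signature artifact — the juxtaposed-cell failure mode of
   nucleus-seeded segmentation. A cluster with no positive marker is
   discarded as an uninterpretable null phenotype.
3. **Scoring.** `score(type) = #POS matched - #POS missed - penalty x #NEG
   violated` (penalty 1), argmax over the signature rows, ties broken by
   the fixed row order; the transitional AT co-positivity rule overrides
   the argmax.

Discarded clusters are excluded from every composition denominator.

## Quantification, time course, TMA adequacy

`composition()` reports per-sample percentages over classified cells for
the 11 fine types, the 8 major types (alveolar subtypes merged), and the
two published aggregates (total alveolar; all stromal = stromal +
myofibroblast/SMC, which stay separate otherwise). Group statistics are
unweighted across-sample mean +/- SD. `marker_by_type()` gives Tukey
boxplot statistics (1.5 IQR whiskers) of rescaled intensity per type and
group. `timecourse_report()` adds the L1 distance of each timepoint's mean
fine composition from control, the metric used to express "day 28 is close
to saline".

The virtual-TMA adequacy test operationalizes "all main populations found
in the whole section are rediscovered in the core": each core is
re-clustered and re-classified with the same configuration, and a
population counts as identified when some cluster is assigned to it with
at least 20 cells and signature completeness of at least 0.6 (the fraction
of the type's POS markers called positive — the original criterion was
visual t-SNE inspection, so thresholds are configurable). The packaged
validation experiment plants 4 cores of 1 mm and 4 of 2 mm on a jittered
grid over a 5.2 x 5.2 mm synthetic section (~50k cells, the whole-slide
scale). Under the default generator, 2 mm cores are adequate and 1 mm
cores are not: with ~1,500 cells a 1 mm core carries only 10-40 cells of
the rarest types (stromal, myofibroblast/SMC, neutrophil), below what
k = 30 graph clustering can resolve into communities. The 4%-frequency
macrophage population (~60 cells at 1 mm) remains above that limit in this
generator — its published 1 mm failure suggests real-data noise sits above
ours for sparse hematopoietic populations; we chose not to inflate the
noise model post hoc to force that specific coincidence, and the package
reports the per-population identifiability so users can see exactly which
populations a core size loses.

## Scale choices and determinism

Image-path runs (registration through features) operate on full 2 mm cores
(~2400 px square, 38 images, about 4-5 minutes end to end on one CPU);
whole-section-scale experiments (TMA validation, treatment cohorts) use the
generator's table path — identical placement and intensity model with an
explicit spillover term instead of pixel rendering — because rendering and
segmenting dozens of 5 mm sections would add hours of pure pixel work
while testing nothing the core-scale image path has not already
established. Cohort tests use 2,000-2,500 cells per mouse, 2-3 mice per
group, 3 seeds.

Everything is seeded: stage seeds derive deterministically from one master
seed (`derive_seed()`), identical configuration + seed reproduces
byte-identical CSV outputs, and each cluster result records its k and seed.
Known degenerate inputs are defined behaviors, not crashes: blank images
segment to empty masks, zero-cell fields produce background-plus-AF images
and empty (but fully-typed) tables, single-cluster positivity falls back to
an absolute cutoff, and identical embedding rows are jittered by 1e-9
before t-SNE/UMAP.

## Known limitations

* The signature table, artifact compartments and positivity defaults encode
  this panel; other panels need their own `targets` lists and lineage
  grouping.
* Per-cluster (not per-cell) classification: cells inherit their cluster's
  label, as in the original workflow; a mixed cluster mislabels its
  minority members.
* Rigid registration only; no elastic deformation, no .ndpi ingestion.
* The generator does not model optics (PSF), structured AF, staining
  failure, stripping damage, or 3-D tissue; conclusions about real-slide
  performance require real slides.
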