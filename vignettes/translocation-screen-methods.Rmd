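---
title: "Methods: simulating and analyzing a nuclear-retention translocation screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing a nuclear-retention translocation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rushscreen)
```

## The assay this package models

A danger-signal protein such as HMGB1 normally resides in the nucleus; its
exodus to the cytoplasm and release from the cell is an immunologically
important event, and drugs that trigger it are worth finding at scale. A
retention-hook ("hook-and-release") biosensor makes the event visible: the
protein is fused to a streptavidin-binding peptide and GFP, and held in
nuclear puncta by a nuclear-targeted streptavidin hook. Adding biotin
outcompetes the hook-reporter interaction, releasing the reporter, which —
in the absence of any drug — stays diffusely nuclear. A genuine
translocation inducer moves the released reporter into the cytoplasm; a
compound that merely kills cells or quenches fluorescence dims the nuclear
signal in *both* cue conditions. Running every compound once with and once
without the cue therefore separates specific release from nonspecific
signal loss, and nuclear pyknosis (a small, condensed, brightly staining
nucleus in the DNA dye) flags frank toxicity.

`rushscreen` implements the complete numeric tail of such a screen —
segmentation, per-cell features, plate normalization, Z-scoring,
differential hit calling, ranking, clustering — plus a ground-truthed
synthetic plate generator, so every stage can be validated end to end with
known answers.

## The synthetic plate generator

The generator is first-class, tested code, not a fixture. Each well is a
mixture of four rendered phenotypes:

| phenotype | nuclear pool | cytoplasmic fraction | nucleus |
|---|---|---|---|
| `punctate_retained` | 8 Gaussian puncta (sigma 2 px) carrying 85% of the nuclear pool | 0.02 | normal |
| `diffuse_nuclear` | uniform | 0.05 | normal |
| `translocated` | uniform | 0.40 | normal |
| `pyknotic` | uniform, total x0.2 | 0.05 | radius x0.55, dye x1.8 |

A compound's ground-truth class maps to mixtures by the cue logic:
inactive wells are punctate without the cue and diffuse with it; a
specific releaser converts an `effect` fraction (default 0.6) of cue-side
cells to `translocated` and *never* produces translocated cells without
the cue; a nonspecific-loss compound keeps inactive mixtures but scales
every reporter total by `1 - effect` (default 0.7) in both conditions; a
toxic compound makes an `effect` fraction (default 0.6) pyknotic in both
conditions.

Rendering and noise. Cells are anti-aliased disks: nucleus radius ~
truncated normal (mean 14 px, CV 0.15, clamped to ±3 SD), cell body a
concentric disk at 1.9x the nucleus radius. Per-cell reporter totals are
log-normal (CV 0.25) around `mean intensity x nucleus area`, split between
nucleus and cytoplasmic annulus by the phenotype's cytoplasmic fraction
and renormalized over in-field pixels, so with noise and background off
the rendered integral equals the drawn total exactly (16-bit quantization
aside). The camera model adds a constant background (40 counts) and
zero-mean Gaussian noise with variance `gain x mean + read_sd^2` (gain 1,
read SD 3) — the stated second-moment model of photon plus read noise,
sampled in one pass — then quantizes to integer counts in [0, 65535].
Quantizing makes the TIFF round trip lossless, which is what lets staged
(on-disk) and streaming pipeline runs agree bit for bit.

Field geometry. Fields are 768x768 px at 0.65 µm/px with ~150 cells per
field and 4 fields per well. At this density cell bodies cover roughly
half the field, which matches adherent screening cultures near confluence,
and a full 384-well x 4-field simulation stays at desk speed (about eight
minutes on one core). Nucleus centers are placed by rejection sampling
with zero allowed nucleus-nucleus overlap (touching permitted). Cell
density and exposure settings have no canonical published values, so
these are declared defaults, all exposed in `default_config()`.

Seeding. One run seed; each field derives its own stream as
`field_seed(seed, plate, well, field)` (a fixed linear hash below 2^31),
so any single field is independently reproducible and wells never share
streams.

What the generator does *not* emulate: optics beyond Gaussian puncta (no
PSF convolution), illumination shading, debris and segmentation-hostile
morphologies, focus drift, well-edge effects. Passing the recovery tests
therefore demonstrates the correctness of the numeric pipeline on its
stated model, not robustness to every failure mode of real microscopy.

## Segmentation

`segment_nuclei()` is the standard high-content nucleus chain: Gaussian
smoothing (sigma 1 px), Otsu global threshold (run on a 3x-subsampled
histogram for speed), hole filling, connected components, then
distance-transform watershed splitting. Splitting is applied selectively:
a connected component is re-labelled on its bounding box only when its
area exceeds `1.2 x pi x maxdist^2` (incompatible with one convex
nucleus) or the area cap; isolated disks never split, so the result
matches a full-field watershed at a fraction of the cost. Objects outside
[120, 1400] px² are removed; labels are renumbered 1..K in raster order of
their centroids. The smoothing default of 1 px keeps the Otsu boundary
within half a pixel of the half-maximum edge; larger sigmas systematically
dilate masks (precision on a noiseless planted disk drops below 0.95 near
sigma 2, which is why 1 is the default).

`segment_cytoplasm()` grows cell bodies from the nucleus seeds over the
thresholded cytoplasmic-dye mask by nearest-nucleus (distance-based)
assignment — the classic distance-constrained secondary-object method —
clipped to 32 px around the nuclei, implemented with a two-pass
feature/distance transform. For the convex, disk-shaped bodies this model
produces, the assignment coincides with a seeded watershed restricted to
the mask, and it is exactly deterministic. Cytoplasm `k` is body `k` minus
*every* nucleus, so the maps are pixel-disjoint and share ids. A nucleus
whose dye threshold contributes no pixels still receives a 6 px fallback
annulus (configurable, 0 disables) so intensity features are always
defined; with the fallback disabled, a zero cytoplasmic-dye field yields
empty cytoplasm regions, as the strict threshold semantics dictate.

## Per-cell features

Background is the per-field median of pixels in neither map — robust and
parameter-free — subtracted from the reporter and floored at 0. Intensity
features are plain means over mask pixels. The cytoplasm/nucleus ratio is
flagged `NA` when the nuclear mean is below `1e-6` counts.

Granularity is the white top-hat fraction: top-hat of the reporter with a
disk structuring element (radius 5 px, about 2.5 punctum sigmas), summed
over the nucleus and divided by the reporter sum there, clamped to [0,1].
The score is invariant to multiplying the raster by any positive constant
and strictly decreases under a constant additive offset (the top-hat is
offset-invariant while the denominator grows) — hence background
subtraction first. A punctate nucleus scores ≈ 0.6-0.7 with these
defaults; a diffuse one ≈ 0.01.

Pyknosis is called per cell against the plate's negative-control cells:
area below 0.5x the control median *and* nuclear-dye mean above 1.3x the
control median. Both condensation features must agree, which keeps small
dim debris and bright large nuclei out. Generator pyknosis (radius x0.55 →
area x0.30, dye x1.8) sits far inside both thresholds.

Well summaries are unweighted means over all cells pooled across the
well's fields; wells with fewer than 20 cells are flagged `low_count`,
carried through the matrices, but excluded from normalization populations
and hit calling — a toxic well with few survivors should be caught by the
pyknosis readout, not by a noisy translocation score.

## Normalization and hit calling

Intra-plate: each feature is divided by its mean over the plate's included
(non-low-count) wells of the same cue condition, making every plate x
condition group mean exactly 1 and cancelling global intensity offsets
between plates. A plate whose feature mean is zero is a degenerate-plate
error naming plate and feature, never a silent NaN.

Inter-plate: the classic standardized score `Z = (Xi - mean(Xall)) /
std(Xall)` per feature within each cue condition, with the population
(divide-by-N) standard deviation — the convention is fixed and tested
because bit-exactness requires a choice, though at n ≈ 380 the difference
from the sample convention is negligible. The default population is the
sample wells only (`z_population = "samples_only"`): control wells are
numerous and quiet, and including them would compress the sample variance
and inflate every z. Controls are still transformed with the population's
parameters.

Hit classification applies, in order of precedence: **toxic** if the
cue-side pyknosis z ≥ 2 (a dying cell can show cytoplasmic signal, so
toxicity outranks translocation); **nonspecific_loss** if the nuclear
reporter z ≤ −2 in *both* conditions; **specific_releaser** if the
cytoplasmic reporter z ≥ 2 with the cue and |z| < 1 without it;
**inactive** otherwise. Thresholds (2 / 1 / 2) are conventional screening
cutoffs, all configurable; the ranking (`rank_score = z_cyto_plus −
max(z_cyto_minus, 0)`, specific releasers only, ties broken
lexicographically) reproduces a top-k presentation independent of the
threshold choice. These z-thresholds presuppose a mostly-inactive library;
on a toy plate where a third of the compounds are active the population SD
is inflated by the hits themselves and sensitivity drops — the package's
own demo test plants 3 actives among 16 compounds for exactly this reason.

Clustering of response profiles uses Pearson distance `d = 1 − r` (so
identical profiles sit at 0 and sign-flipped ones at 2) with average
linkage, via `stats::hclust`; the tests check the merge heights against an
exhaustive enumeration for n ≤ 5 and the dendrogram exports to Newick.
Zero-variance profiles are errors naming the profile, not silent drops.
Replicate statistics (`dose_time_summary()`) report mean, SEM
(sample SD / sqrt n) and a two-tailed equal-variance Student's t test with
the conventional star thresholds; Welch is available behind a flag.

## Numerical choices and degenerate inputs

* All RNG flows through `withr::with_seed`; camera noise uses the
  Marsaglia polar sampler on R's uniform stream, so results are
  reproducible under a seed without touching the session RNG state.
* Rendered images are integers; every raster written to disk (fields and
  label maps) round-trips 16-bit TIFF losslessly, and the analysis stage
  always reads the serialized well table, so `run_screen()` output is
  bit-identical across reruns and between streaming and staged execution.
* Empty fields, all-zero rasters, zero-cell wells, constant feature
  columns, missing cue conditions and zero-variance profiles all have
  defined behavior (empty outputs or named errors) exercised in the test
  suite.
* Problem sizes in the tests: the end-to-end recovery runs one full
  384-well plate at 4 fields/well and ~150 cells/field (≈ 230,000 cells);
  unit fixtures use 128-512 px fields. The t-test calibration uses 10,000
  null replicates; the truth-table oracle grid has 10,584 combinations
  spanning every rule boundary at ±1e-6.

## Known limitations

* The generator's phenotype intensity model is deliberately simple
  (log-normal totals, disk geometry); it fixes the *contrasts* the
  pipeline must recover, not absolute microscope realism.
* Hit calling assumes both cue conditions exist for every compound x
  dose; incomplete pairs are errors rather than imputations.
* The distance-based cytoplasm growth is exact for convex cell bodies;
  strongly concave cells (not produced by the generator) would be better
  served by intensity-geodesic propagation.
* Granularity, as a top-hat fraction, saturates for very bright compact
  puncta; it is a ranking feature, not a calibrated physical quantity.
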