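---
title: "Predicting tumour tissue of origin from DNA methylation images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tumour tissue of origin from DNA methylation images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylCUP)
```

## The problem

Cancer of unknown primary (CUP) is metastatic cancer whose organ of origin
cannot be established by standard workup. Because treatment is chosen by
primary site, a molecular classifier of tissue of origin has direct clinical
value. DNA methylation is well suited to the task: beta values (the fraction
of methylated signal at a CpG, bounded in [0, 1]) are strongly
tissue-specific, largely retained in metastases, and less sensitive to batch
effects than expression data.

methylCUP implements a complete pipeline that turns a probes-by-samples beta
matrix into per-sample grayscale "methylation images" and classifies them
with a small vision transformer (ViT):

1. **Preprocessing** — probe presence filter, per-probe median imputation,
   optional top-variance restriction, recoding of cancer types into origin
   classes, stratified train/validation/test split.
2. **Differential CpG (DMC) panels** — per-class probe selection, run
   separately inside the non-squamous and squamous histology groups.
3. **IGTD embedding** — assignment of each panel's probes to the cells of a
   fixed 2-D grid so that similar probes land on nearby pixels.
4. **Imaging** — per-sample rendering of betas onto the grids, resize of the
   squamous half, merge, and 8-bit quantisation.
5. **ViT classification** with per-sample attention maps.
6. **Evaluation** — confusion matrices and one-vs-rest precision / recall /
   F1 with support-weighted averages.

## Preprocessing model and defaults

A probe is kept when at least 80% of samples carry a measured value
(`min_frac = 0.8`, inclusive at the boundary). Remaining gaps are filled
with the probe's median across measured samples. The variance filter keeps
the `k = 10000` probes with the largest *population* variance (divide by n);
ties break lexicographically by probe ID so results do not depend on matrix
order. The stage order filter → impute → select is enforced: imputing first
would erase the missingness that the presence filter needs, so the filter
refuses (in strict mode) a matrix imputed without a prior filter. Re-running
the correctly ordered chain is a no-op, which the test suite asserts.

Cancer types are recoded by a `ClassMap`. The default map covers 29 retained
TCGA solid-tumour types (two small cohorts, adrenocortical carcinoma and
uveal melanoma, are excluded) and folds them into 18 origin classes by organ
or histology: seven organ groups (colorectal, oesophagogastric, kidney,
hepatobiliary, brain, soft tissue, gynecologic), nine singleton organ
classes, and the five squamous-histology types. The map is a reconstructed
fixture: public sources give the organ/histology groupings but not a
per-type table, and mixed-histology types (esophageal, cervical, bladder)
can in reality be split at the sample level, which a type-level map cannot
express. Under the default map the five squamous types are BLCA, CESC,
ESCA, HNSC and LUSC; head & neck and bladder are the two classes without a
non-squamous counterpart. Any other mapping can be supplied as YAML via
`read_class_map()`.

Splitting is stratified by origin class with largest-remainder rounding, so
per-class fractions deviate from 60/20/20 by at most one sample; whether to
stratify was an open choice, made here to stabilise per-class metrics at
small n. Classes with fewer than three samples go wholly to training with a
warning. Whether the top-10,000-variance restriction should feed panel
selection is a second open choice; the default runs DMC selection on the
full filtered probe set, with `top_k_variance` available to restrict it.

## DMC panels

Within a histology group, each class is contrasted against *all other
samples of the same group* (never the whole cohort): per probe, the
difference of medians (in-class minus out-of-class) and a two-sided
Mann-Whitney U test. Probes with p < 0.001 (uncorrected, matching the
method's published screening rule) are ranked by decreasing |Δmedian| —
the quantity the selection foregrounds — with smaller p and then probe ID as
tie-breaks, and the top k are taken: k = 136 per non-squamous class and
k = 90 per squamous class by default, giving 17 × 136 = 2,312 and
5 × 90 = 450 probes when 17 and 5 classes are present. Classes are
processed alphabetically and each class excludes probes already claimed, so
a panel is duplicate-free and its flat probe list (class-concatenation
order) is part of the serialised contract — the image layout depends on it.
Both hyper- and hypomethylated probes are eligible (absolute difference).

The U test uses the exact Wilcoxon distribution when both arms have at most
20 observations and no ties, and otherwise the normal approximation with
tie correction and no continuity correction; two fully tied samples give
p = 1. The test suite checks both paths against a label-permutation oracle
with 100,000 resamples.

## IGTD embedding

Pairwise Euclidean distances between panel probes (across training samples
only) and between grid-cell coordinates are each converted to ranks of the
n(n−1)/2 pairs (average ranks on ties). The assignment objective is the sum
over cell pairs of the absolute difference between the feature rank of the
assigned probes and the pixel rank of the cells; a squared variant is
selectable (`variant = "squared"`). The optimiser starts from the identity
order, and each iteration picks the cell with the largest error contribution
among cells not examined within the last `lookback = n/2` iterations,
evaluates swapping its probe with every other cell's, and applies the best
strictly-improving swap — so the error trajectory never increases.

Two refinements address small grids, where plain 2-swap descent provably
stalls: after the swap neighbourhood is exhausted on instances of ≤ 64
cells, strictly-improving 3-cycles are tried; and on instances of ≤ 100
cells the climb is repeated from 15 seeded random initial orders, keeping
the best assignment (the recorded trajectory tracks the incumbent best and
remains non-increasing). Full-size panels run the single identity-start
climb with the default budget of 5,000 iterations. On exhaustible instances
(n ≤ 8) the suite compares the final error with the true optimum from
enumerating all permutations.

The default grids are 68 × 34 for the 2,312-probe panel and 30 × 15 for the
450-probe panel. For other panel sizes `grid_for_panel()` picks the divisor
pair closest to the 2:1 aspect ratio; the non-squamous grid must satisfy
rows = 2 × cols so that the merged image is square.

## Imaging

A sample's image places its beta value on each assigned cell, resizes the
squamous grid to the non-squamous grid shape (nearest-neighbour by default,
preserving the blocky per-probe semantics; bilinear available — both via
EBImage), concatenates the halves column-wise with the non-squamous part on
the left (a fixed, recorded orientation), multiplies by 255 and replicates
the result over three identical channels. Quantisation rounds half away
from zero (0.5 → 128) for bit-exact reproducibility. Values outside [0, 1]
are errors, never clamped. External samples lacking a panel probe can fall
back to a supplied per-probe beta (intended: training medians) or fail
hard. Every image stack carries a fingerprint of the assignments that
produced it; a model refuses to predict a stack with a different
fingerprint, since pixel semantics would silently differ.

## The vision transformer

The default geometry follows the published architecture: 68 × 68 × 3 input
cut into 4 × 4 patches → 289 tokens ("17 × 17" is read as the patch *grid*,
since 68/4 = 17 and 17² = 289); linear projection to dimension 256 plus
learned position embeddings; 8 pre-norm transformer blocks with 4 attention
heads and a GELU MLP of 512 → 256 units; a final layer norm; an all-token
flatten (no CLS token — the whole final block output feeds the head, as
described) into a GELU head of 1024 → 512 units and a softmax output.
Training uses categorical cross-entropy with AdamW (learning rate 1e-4,
batch 100, 14 epochs), dropout 0.1 in attention and MLPs and weight decay
1e-4 — the last three are unstated in the source description and fixed here
as explicit defaults — keeping the parameters of the epoch with the best
validation accuracy. Forward and backward passes are implemented directly
in R on BLAS matrix products; the backward pass is verified against central
finite differences in the test suite.

`vit_config_scaled()` is the desk-scale variant used by the tests: 2
blocks, projection 64, 5 epochs, batch 16, learning rate 3e-3, no dropout.
The larger learning rate compensates for the small step count
(≈ 45 updates); with the full model's 1e-4 a 5-epoch run barely leaves
initialisation.

Attention maps take the final block's softmax attention, average it over
heads and query tokens (each row sums to 1, so the aggregated map sums to 1
over the patch grid), reshape to the patch grid and upsample
nearest-neighbour to image size.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes: probe baseline means drawn from Beta(0.5, 0.5) (bimodal like real
methylation) squeezed into [0.05, 0.95]; per-sample betas drawn from a Beta
distribution with the probe's mean and precision 60 (sd ≈ 0.06 at
mid-range); per class a disjoint set of implanted probes whose in-class
mean is shifted by ±`effect_delta` (alternating hyper/hypo), with implanted
baselines kept away from the boundary so the realised median shift equals
the nominal effect; missingness completely at random; and optional
"metastatic" samples drawn from the same class distributions with lower
precision (factor 0.6) — the generator's rendering of the observation that
metastases retain the primary tumour's methylation profile.

The default study conditions are 6 classes (3 squamous), 40 primary samples
per class plus 25% metastatic, 5,000 probes, 50 implanted probes per class
at `effect_delta = 0.4`. Both histology groups keep at least three classes
deliberately: in a 2-class group the in/out contrast is symmetric, the two
classes' implanted probes become statistically interchangeable, and
per-class recovery is arbitrary regardless of effect size.

What the generator does *not* emulate: probe-level correlation structure
(CpG islands), batch and platform effects, dye bias, cross-hybridising
probes, class imbalance, or tumour purity gradients. Passing tests
demonstrate that the machinery recovers implanted structure under clean
conditions; they do not certify performance on real cohorts, which is why
published real-data accuracies are out of scope for this package's checks.

## What the automated checks compute

* Structural constants, recomputed from scratch on synthetic cohorts with
  17 + 5 classes: panel sizes 2,312 and 450; grids 68 × 34 and 30 × 15;
  merged 68 × 68 × 3 images; 289 patches; 29 types → 18 classes with a
  cohort head count of 8,233 − 79 − 80 = 8,074; 10,000 probes kept by the
  variance filter.
* Oracle equivalence: rank matrices, assignment error, Mann-Whitney U,
  imputation and confusion metrics against brute-force reimplementations;
  IGTD against exhaustive permutation search at n ≤ 8.
* Invariants: non-increasing IGTD trajectories; quantisation endpoints
  0 → 0 and 1 → 255; attention rows summing to 1; weighted recall equal to
  overall accuracy.
* Desk-scale recovery on the default cohort: per-class recall of implanted
  probes ≥ 0.95; scaled end-to-end test accuracy ≥ 0.9 with the held-out
  metastatic accuracy within 5 points of the primary test accuracy, over
  three seeds; attention entropy below the uniform bound.

`scripts/acceptance.R` re-runs these computations at a user-supplied seed
and writes the resulting numbers as JSON. Problem sizes (22-class cohorts
of 12 samples per class for the structural checks; the 6-class default
cohort for recovery) were chosen so the whole suite runs in a few minutes
on one CPU while every quantity is still computed, never asserted.

## Known limitations

* The default ClassMap is a type-level reconstruction; sample-level
  histology splits of mixed types are not representable, so under it the
  non-squamous group holds 16 of the 18 classes. Panel construction is
  class-count-agnostic and takes whatever classes the annotation provides.
* The ViT trains on CPU in plain R; the full 8-block, 75M-parameter
  configuration is practical for inference-scale experiments but slow to
  train at cohort scale — the scaled configuration exists for exactly that
  reason.
* IGTD restarts are limited to small instances; large panels may retain the
  greedy climb's local optimum (as the underlying algorithm does).
* A 420-versus-450 discrepancy exists in public descriptions of the
  squamous panel size; 450 = 5 × 90 = 30 × 15 is the arithmetically
  consistent value and is the default here.
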