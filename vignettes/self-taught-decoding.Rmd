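---
title: "Self-taught learning for decoding fMRI statistic maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-taught learning for decoding fMRI statistic maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stldecode)
```

## The problem

Task-fMRI analyses summarise brain activity as *statistic maps*: 3D volumes
of voxelwise T or Z values for a contrast of task conditions. Decoding —
predicting the cognitive condition from the map — is a natural supervised
problem, but labelled neuroimaging datasets are small (tens to hundreds of
subjects) while the volumes are large, so deep 3D classifiers trained from
scratch overfit and generalise poorly across individuals.

Public repositories, however, hold tens of thousands of *unlabelled*
statistic maps. `stldecode` implements the self-taught-learning strategy
for exploiting them: pretrain a 3D convolutional autoencoder (CAE) to
reconstruct unlabelled maps, transfer its encoder weights into a 3D
convolutional classifier (CNN), and fine-tune on the labelled task. The
package covers the whole pipeline — metadata curation, preprocessing,
subject-wise cross-validation plans, model building/training, transfer and
freezing ablations, evaluation, and between-subject feature-map analysis —
plus a synthetic statistic-map generator so every stage is testable without
any download.

## Models

Both architectures ingest volumes on a common 48 × 56 × 48 grid at 4 mm
spacing. The encoder stacks 4 or 5 conv blocks, each a 3×3×3 convolution
with stride 2 and padding 1, followed by 3D batch normalisation and a leaky
ReLU (negative slope 0.01, the conventional default; the reference
design leaves it unspecified). Channels are 64→128→256→512 for the
4-layer model (latent 512 × 3 × 4 × 3 = 18,432) and 32→…→512 for the
5-layer model (latent 512 × 2 × 2 × 2 = 4,096). A `width_multiplier`
scales all channel counts, giving desk-scale models with identical shape
structure.

The decoder mirrors the encoder with stride-2 transposed convolutions.
Kernel sizes are derived per dimension so each decoder layer exactly
inverts the conv shape map `o = floor((n + 2p - k)/s) + 1` via
`n = (o - 1)s - 2p + k`; on the default grid this reproduces the
(4,3,4),(4,4,4),(4,4,4),(4,4,4) and (3,4,3),(4,3,4),(4,4,4),(4,4,4),(4,4,4)
kernels of the reference design. The final decoder layer has no batch norm
and applies tanh, so reconstructions live in [−1, 1] like the normalised
inputs. (A sigmoid, the other bounded candidate, cannot reach negative
values and so cannot match the normalised input range; it remains
available via `output_activation` for sensitivity checks.)

The classifier is the encoder plus one dense layer with softmax. Default
initialisation is Kaiming-uniform with parameter a = √5 — weights and
biases drawn from U(±1/√fan_in) — matching the usual framework default.
`transfer_weights()` copies the conv weights and biases of the first
`n_transferred` encoder blocks from a trained CAE; batch-norm parameters
are *not* transferred unless requested, following the literal description
("weights and bias of the convolutional layers"). `freeze_prefix()`
excludes the first blocks from gradient updates and runs their batch norm
in inference mode, so frozen parameters (including running statistics) are
bitwise invariant during fine-tuning — asserted programmatically after
every freeze-sweep fold.

Training uses Adam (lr 1e-4 unless stated), MSE for reconstruction and
cross-entropy for classification, with no schedule, weight decay, early
stopping or augmentation, and final-epoch parameters are evaluated. Batches
are reshuffled each epoch with a seed derived from the run seed, so a run
is fully determined by (seed, config, data) on a fixed machine.

### Numerical implementation

No deep-learning framework is available to R here, so the conv stack is
implemented in the package: a double-precision set of granular operators
(the reference path) and a fused single-precision training engine that
lowers convolutions to BLAS `sgemm` through im2col patch matrices. The
engine is validated in the test suite against the reference path and
against finite-difference gradients. The Adam update itself runs in double
precision in R. Single-precision training is the framework norm; the two
paths agree to float tolerance (~1e-6 relative on gradients).

## Preprocessing

`preprocess_map()` applies, in order: trilinear resampling onto the
analysis grid (non-finite voxels zeroed first, out-of-volume samples 0);
min–max normalisation `x ↦ 2(x−m)/(M−m) − 1` with the minimum and maximum
taken over *in-mask* voxels (so background zeros never dominate the
range; a constant map maps to 0); and brain masking (out-of-mask voxels
exactly 0). The pipeline is idempotent on its own output. A
sign-preserving alternative `x ↦ x/max|x|` is available via
`method = "symmetric"` because a "between −1 and 1" requirement admits both
readings. The mask defaults to an ellipsoid inscribed in the grid for
synthetic work; a real template mask is accepted via
`read_brain_mask()`.

## Curation

`filter_metadata()` applies the repository inclusion rules: modality
fMRI-BOLD, valid metadata, MNI-registered, T/Z statistic type, not
thresholded, and no raw-contrast filenames. The filename rule splits the
basename on non-alphanumeric characters and rejects tokens matching
`^(con|cope)[0-9]*$` — this catches SPM `con_0001` and FSL `cope3` while
keeping legitimate names like `contrast_of_interest.nii` — and matches
`SetA_mean`/`SetB_mean` as substrings since they span an underscore. A
plain substring mode is available. The per-rule rejection counts are
returned alongside the kept manifest, and filtering is idempotent and
non-mutating.

`split_pretraining()` splits the curated corpus 80/20 *at map level* (the
unsupervised stage uses no labels, so subject leakage is immaterial), with
`round(fraction·N)` maps in training. For the published corpus size
(28,532) this gives 22,826/5,706 where the reference analysis reports 22,772/5,760 —
an inconsistency in those counts; the package follows the
arithmetic rule.

## Subject-wise partitioning

All supervised splits are by subject. `split_holdout_by_subject()` makes
the validation/test holdout; `assign_subject_folds()` builds 5-fold plans
with fold sizes within one subject (earlier folds take the extras);
`nested_subsample_folds()` draws N/k subjects per fold to create nested
subsets (50 ⊂ 100 ⊂ 200 ⊂ all) that preserve fold indices, so a model
trained on 4 folds of any subset can be tested on the *global* plan's
remaining fold with zero subject overlap — the guarantee is asserted for
every emitted configuration. For multi-study data,
`combine_study_folds()` holds out 50% of each study's subjects per side
and combines the n-th folds across studies, and
`extract_small_multistudy()` keeps studies with more than `min_subjects`
subjects and draws `per_fold` subjects per fold per study per side
(defaults 20 and 2, giving 10 subjects per study per side). Fold plans
serialise to JSON keyed by subject id. Folds are indexed 0..k−1, matching
the serialized form.

Whether the validation-side subsamples used the identical nested
procedure as the test side is left open in the reference design; the same
procedure is assumed for both. Testing on the subset's own fold (rather
than the global fold) remains available by passing the subset plan as
`global_plan`.

## Evaluation

`classification_metrics()` reports accuracy, macro precision/recall/F1
(per-class F1 = 2PR/(P+R), zero where P+R = 0) and per-class accuracy
(= per-class recall); classes absent from the truth contribute zero to the
macro averages with a warning. Macro averaging for precision/recall is a
choice — the reference analysis specifies macro explicitly only for F1 — made for
consistency with its class-imbalance discussion. Fold summaries are mean
and SEM (sample sd/√n). `paired_onetailed_ttest()` is the paired
dependent-samples t statistic on fold-matched differences with n−1 degrees
of freedom (4 for the 5-fold design) and a one-tailed p; the default
alternative is "pretrained exceeds default", consistent with reporting
negative t values for (default − pretrained). Degenerate cases are
explicit: identical vectors give t = 0, p = 0.5; zero-variance nonzero
differences give a signed infinite t.

`reconstruction_correlation()` is the Pearson correlation over in-mask
voxels, with zero variance raised as an error rather than silently 0.

## Explainability

`extract_layer_features()` returns a layer's post-activation tensor in
inference mode. `between_subject_feature_correlation()` flattens each
subject's feature tensor to one vector (all channels concatenated, so a
layer's features form one object per subject; per-channel correlation can
be had by slicing the tensor), computes
Pearson correlations for all unordered subject pairs of one class, and
summarises by the mean: higher mean correlation means features less
sensitive to individual differences, i.e. more generalizable. Feature
vectors are not z-scored beforehand (Pearson centres and scales
internally). Zero-variance vectors skip their pairs with a warning.

## The synthetic generator

`generate_labeled_collection()` and `generate_pretraining_corpus()`
emulate the structure the analysis assumes, not the biophysics. Each class
is a set of isotropic Gaussian blobs (centres uniform over the brain mask,
widths 8–14 mm, z-scale peak amplitudes 4–8, 15% negative) rendered on the
grid; in the single-study regime classes are nested in parent tasks and
share their task's blobs, so task decoding is easier than contrast
decoding. Subject effects are a rigid integer-voxel shift (sd 1 voxel) and
a multiplicative log-normal gain (sd 0.15); study effects are a gain (sd
0.2) and a smoothness jitter (sd 2 mm) — the cheapest mechanisms that
produce between-subject feature decorrelation and between-study
heterogeneity. Additive Gaussian noise is smoothed at 8 mm FWHM and
rescaled to unit z-scale sd. Values are clipped to |z| ≤ 12 and zeroed
outside the mask. Subject and study effects derive deterministically from
the corpus seed and the identifier, so they are fixed across a subject's
maps. The defaults are calibrated so that a nearest-template assignment
recovers ≥ 90% of labels — the decoding task is learnable but not trivial
under subject-level nuisance.

The pretraining corpus draws from throwaway templates (disjoint from any
labelled collection, preserving the self-taught premise that the
unlabelled data's classes are unknown) and injects a configurable fraction
of contaminant records exercising each curation rule, with the ground
truth in a hidden `.contaminant` column.

What the generator does *not* model: realistic hemodynamics or anatomy,
surface data, multilabel concepts, registration error beyond rigid shifts,
or scanner/pipeline artefacts. Passing tests therefore demonstrate the
pipeline's correctness and the transfer mechanism's behaviour under
controlled variability — not performance on real repository data.

## The reference benchmark and problem sizes

`benefit_benchmark()` is the package's desk-scale analogue of the
small-sample experiment: a single-study collection with 23 contrasts in 7
tasks and 25 subjects per repetition, split 20 training / 5 test subjects
by subject; quarter-width models trained 30 epochs at lr 1e-4, batch 32;
3 repetitions with distinct data and initialisation seeds, all derived
from one master seed. Both initialisations see identical data. Reported:
mean test accuracy per initialisation, and the fraction of
(repetition, class) cells in which the pretrained model has the higher
mean layer-3 between-subject feature correlation over the 5 test subjects
(10 pairs per class).

Two desk-scale choices deserve justification:

* **Depth.** The 5-layer architecture is used for both initialisations.
  The 5-layer model is the depth reported best for pretrained classifiers,
  with the strongest self-taught-learning effect attributed to the deeper,
  more compressed architecture; a paired comparison requires one common
  architecture, so the depth that benefits from transfer is the relevant
  one.
* **CAE pretraining schedule.** The corpus here is ~75 curated maps, not
  22,772, so the full-scale lr 1e-4 over a comparable epoch count would
  leave the encoder at its random initialisation — no self-taught learning
  at all. The pretraining stage is therefore calibrated by its own
  criterion, a held-out reconstruction plateau: batch 8, lr 1e-3, 150
  epochs. The classifier stage keeps the benchmark's fixed lr 1e-4 and 30
  epochs.

Problem sizes throughout the tests (16³ unit-test grids, the 100-map
corpus, 25-subject collections, quarter width) are the package's chosen
desk scale: large enough to exercise every contract, small enough to run
on one CPU core in minutes.

## Known limitations

* The conv engine is CPU-only and single-threaded beyond BLAS; the
  published full-scale experiments (tens of thousands of maps, hundreds of
  epochs) are out of its intended range.
* Reconstruction quality achievable on the tiny synthetic corpus is far
  below the published 86.9%/77.8% correlations, which required 22k
  training maps; the pipeline reports whatever its inputs support.
* The generator's nuisance model is deliberately minimal; effect sizes of
  the transfer benefit on real data cannot be extrapolated from it.
* Multilabel concept annotation is collapsed to single labels; the
  manifest carries one concept per map.
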