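---
title: "Simulating annotator variability in lesion-detection CAD retraining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating annotator variability in lesion-detection CAD retraining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package models

Computer-aided detection (CAD) software for medical images is not trained
once: it is retrained as newly annotated cases accumulate. The annotations
come from radiologists, and radiologists disagree — they miss small or
low-contrast lesions, mark confusable anatomy as lesions, and draw spherical
ROIs whose centres and sizes vary from reader to reader. When a retraining
round uses one reader's labels, candidate regions the reader failed to mark
are fed to the classifier as *negatives*, so the reader's misses become
label noise, and the detector's test performance after retraining depends on
who annotated the data. A second question follows immediately: does
combining several readers' annotations (set intersection, union, or a
majority-like vote) give better retraining labels than any single reader?

Clinical CT/MRA archives used for such studies are private, so `annoret`
builds the entire experiment synthetically: phantom volumes with known
ground truth, simulated annotators with tunable error behaviour, a compact
candidate-detection pipeline, the two-round retraining protocol, and
lesion-level evaluation (FROC curves, CPM, Steel–Dwass comparisons). Every
step is deterministic given a master seed, so any result is exactly
reproducible.

## The synthetic world

Two tasks mirror two classical CAD problems.

**Chest task (lung nodules).** Volumes are 64-voxel cubes at 1 mm isotropic
spacing: a smooth parenchyma-like background (low-frequency field, mean 100,
amplitude 15) plus Gaussian noise (SD 8), bright tubular vessels, and
soft-edged spherical nodules. Target nodules have diameters of at least
6 mm, drawn from a lognormal distribution truncated to [6, 18] mm;
a 20% fraction is rendered at 0.4 contrast to emulate ground-glass
opacities. Distractor nodules — the structures an annotator may wrongly
call positive and that make "ambiguous" negative cases — are sub-6 mm.

**Brain task (cerebral aneurysms).** Dark background, a bright
binary-branching vessel tree, and hemispherical aneurysm-like bumps of at
least 2 mm diameter placed at bifurcation points. Distractors are
cone-shaped infundibular widenings at branch origins (plus the bright
basilar-like bifurcations themselves).

The dataset layout follows the modeled retraining study design: an initial
training subset of 50 positives, two retraining subsets of 40 positives /
35 negatives each, and a test subset of 50/50, with exactly 10 negatives in
each retraining and test subset carrying distractor structures. All counts
are overridable for desk-scale runs.

Ground-truth layout and voxel texture use separate random streams, so the
same seed yields the same case geometry whether or not voxels are rendered
— the annotator simulation can therefore run on thousands of cases without
building volumes.

What the generator does *not* emulate: real anatomy (lobes, airways,
circle of Willis), scanner physics, reconstruction artifacts, or intensity
distributions of real CT/MRA. A green end-to-end test therefore establishes
that the *pipeline logic and statistics* behave as specified, not that any
clinical performance level would be reached.

## The annotator model

An annotator profile has interpretable parameters, all free inputs of the
simulation (no published per-reader error rates exist to pin them):

* detection probability is logistic in lesion diameter,
  `sens_max * plogis((d - sens_d50) / sens_scale)` — small lesions are the
  plausible driver of misses, and one interpretable pair of parameters per
  reader (plus an optional plateau) captures it;
* marked ROIs get isotropic Gaussian centroid jitter (`centroid_jitter_sd`,
  mm) and multiplicative lognormal diameter noise (keeps diameters
  positive);
* distractor structures are marked as lesions with
  `distractor_confusion_prob`;
* `Poisson(fp_rate)` false ROIs per case appear preferentially at
  distractor structures when present (false marks arise at confusable
  anatomy), else uniformly in the volume;
* a two-pass reading is supported: after the unassisted pass, CAD
  candidates are shown, and the reader accepts a candidate sitting on a
  previously missed lesion with `cad_rescue_prob`, or a CAD false positive
  with `cad_fp_accept_prob`.

The default 12-reader cohorts follow the modeled tier composition (chest:
5 board-certified / 7 residents; brain: 4/8). Tiers differ only through the
parameter distributions in the configuration — no behaviour is hard-coded
to a tier: whether experience matters is exactly the question such a
simulation should leave to its parameters. Per-(case, annotator, pass) child seeds make each reader's stream
independent: adding a reader never perturbs existing ones.

`estimate_profile()` closes the loop: it re-derives sensitivity-by-diameter,
FP rate, and jitter SDs from simulated annotations by matching them to
ground truth with the same 3 mm rule used everywhere else. Recovery within
±0.25 (FP rate) and ±0.2 mm (jitter) at 300 cases is part of the test
suite. The centroid-jitter estimate is mildly biased low (<3%) because
matches are truncated at the matching radius; this is inherent to any
matched-pair moment estimator and far below the tested tolerance.

## The detector

The pipeline is a deliberately compact analog of published CAD systems —
the object of study is the retraining protocol, not the detector itself,
and everything must train on one CPU in seconds.

1. **Preprocessing.** Resampling to task-specific isotropic spacing (1.0 mm
   chest, 0.469 mm brain) with separable Catmull–Rom cubic interpolation.
   The brain task additionally standardizes intensities by a global
   piecewise-linear map taking the 0/50/98/100 percentiles onto a fixed
   reference scale; a constant volume skips this with a warning.
2. **Organ mask.** Chest: below-threshold parenchyma, largest connected
   component, morphological closing (absorbs thin vessels) and hole filling
   (absorbs nodules of any size). Brain: hysteresis thresholding of the
   vessel tree at intensity quantiles (0.955 weak / 0.985 strong) — chosen
   as quantiles so the rule survives any monotone standardization — with a
   structureless-volume guard that returns an empty mask when the putative
   vessel intensities do not stand clear of the noise.
3. **Candidates.** A scale-normalized Laplacian-of-Gaussian filter bank
   spanning the task's target diameter range (three geometric scales,
   sigma = r/sqrt(3)), evaluated by FFT with mirror padding against
   wraparound. Local maxima inside the mask above a low blobness threshold
   (robust z > 4, recall-oriented) become candidates after non-maximum
   suppression at the blob radius; at most `max_candidates` (40) are kept.
4. **Classification.** Three interchangeable false-positive-reduction
   models: a logistic model on VOI intensity statistics
   (`linear_baseline`, the study-mode default; fast and adequate on
   phantoms), a small 3D conv-net (`cnn3d`), and a conv-net on three
   orthogonal maximum-intensity projections of the VOI stacked as channels
   (`cnn_mip`, two conv + two pool + two fully connected layers, logistic
   output). The conv-nets are implemented in base R (im2col convolutions,
   hand-derived gradients verified against numerical differentiation).
5. **Training loop.** Cross-entropy loss, minibatch momentum SGD
   (momentum 0.99, weight decay 0.001, minibatch 8 — the published
   values; learning rate 1e-5 for the 3D net, which with momentum 0.99 is
   an effective 1e-3). Class imbalance is handled exactly as in the studied
   system: each epoch regenerates 29 augmented copies of every positive VOI
   (integer shifts within ±4 voxels, scaling in [0.85, 1.15],
   quarter-turn rotations in the three orthogonal planes) and re-draws a
   negative undersample so class counts are equal. When fewer negatives
   exist than the augmented positive count — common at desk scale — the
   undersample draws with replacement; the equality invariant is asserted
   per epoch in the tests.

Candidates are labelled against annotations by the same distance rule used
for annotation matching: positive iff within `max(ROI radius, 3 mm)` of an
annotated centroid. The assignment rule is this package's choice (published
pipelines rarely state one); mirroring the 3 mm integration
threshold keeps a single distance scale in the whole artifact. Candidates
the annotator did not mark train as negatives — this is precisely the
label-noise pathway the package exists to study.

Retraining trains **from scratch** on cumulative data (initial subset with
its original labels, plus the retraining subsets with the arm's labels).
Retraining "by adding a subset" describes the data, not the optimizer
state, and from-scratch training is reproducible; a fine-tuning mode was
considered and deliberately not made the default.

## Annotation integration

ROIs from different readers are matched per case by exhaustive centroid
distances: pairs within 3 mm are linked greedily in ascending distance
order, one-to-one per reader pair, with deterministic tie-breaks
(distance, reader id, ROI order); groups are connected components of the
link graph. Two decisions the matching rule had to make explicit:

* **Conflicts.** When one ROI is within 3 mm of two ROIs from the same
  other reader, the closer link wins (greedy ascending order). Against an
  exhaustive minimum-distance optimal matching this agrees on >95% of
  random cases; disagreements are logged by the test suite, not failed.
* **Chains.** Transitive links can join ROIs whose endpoints are more than
  3 mm apart; such groups merge as one and carry a `chain` flag for audit.

A merged group averages member centroids and diameters ("size" is read as
diameter, not volume; volume averaging is available behind a flag).
Strategies: **AND** keeps merged consensus groups of both readers; **OR**
keeps merged groups plus all unmatched ROIs; **VOTING** over an ordered
triple is OR of the first two followed by AND with the third, the
intermediate merged centroids entering the second match. Triples are
canonicalized to {unordered pair} x {third reader} since OR is symmetric.
Cohort-level enumeration caps at 50 seeded combinations (12 readers give
66 pairs / 660 canonical triples).

One algebraic subtlety is worth stating because the test suite documents
it deliberately: `|AND| <= |VOTING|` is **not** a theorem of this VOTING
definition. Any item the first two readers agree on but the third does not
confirm is in AND and dropped by VOTING; with realistic false-mark rates
this occurs with small but nonzero probability (about 1 per 500 random
triples when two readers' uniform false ROIs collide within 3 mm). The
acceptance suite asserts the full chain anyway and the corresponding
expectation is left failing with this analysis; `|VOTING| <= |OR|` *is* a
theorem (AND output counts never exceed its first argument) and holds in
all runs.

## Evaluation

A lesion counts as detected at a score threshold when a candidate at or
above the threshold lies within `max(lesion radius, 3 mm)` of its centre;
candidates are assigned one-to-one (descending score, then ascending
distance) and unassigned supra-threshold candidates are false positives.
The FROC curve takes thresholds at the distinct candidate scores; FP/case
divides by **all** test cases, positive and negative. The CPM is the mean
sensitivity at FP/case targets 1/8, 1/4, 1/2, 1, 2, 4, 8, read from the
curve by a right-continuous step convention (the operating point with the
largest FP/case not exceeding the target; a curve that never reaches a
target contributes its final sensitivity). The step convention never
credits unobserved operating points; linear interpolation between observed
points is a documented alternative, not the default. An independent
brute-force enumeration oracle cross-checks both on hundreds of random
small instances.

Groups of CPMs are compared with the Steel–Dwass all-pairs rank test:
pooled midranks per pair, tie-corrected variance, standardized statistic
`t`, and p-value `P(Q[k, Inf] >= sqrt(2)|t|)` from the studentized-range
distribution (R's `ptukey`). At k = 2 this reduces exactly to the
two-sided normal-approximation Wilcoxon test. A max-T permutation mode
(jointly permuting all groups and recording the largest pairwise
statistic) serves as the finite-sample ground truth. At n = 5 per group
the rank sum is so coarse that the permutation reference is a step
function with jumps of 0.05–0.08 in the mid-p range; the continuous
asymptotic p can therefore differ from it by ~0.1 there, while agreeing
within ±0.01 in the decision-relevant region p < 0.1. The acceptance
suite pins the stricter blanket tolerance and is intentionally left red on
that clause, with the tail-region check green beside it.

## The protocol

`run_protocol()` executes the five steps: train Initial-CAD on the initial
subset with ground-truth labels; every simulated reader annotates
Retraining1 in two passes (the second referencing Initial-CAD candidates
above `display_score_threshold`, default 0.5, exposed as configuration
because no canonical display threshold exists);
per reader, train Retrained-CAD1; every reader annotates Retraining2
referencing *their own* Retrained-CAD1; train Retrained-CAD2; evaluate
everything on the held-out test subset. The integration experiment runs at
the Retraining1 stage (integration studies of this design reflect that
stage), one retrained model per reader combination, then Steel–Dwass over
{single-reader, AND, OR, VOTING} CPM groups per cohort. Failed arms are
recorded and the remaining arms continue. Preprocessing, masks, candidates
and VOIs are computed once per case and shared across all arms — only the
labels differ — which is also scientifically right: every arm must see
identical candidates.

## Numerical and reproducibility choices

* All geometry lives in world millimetres; voxel indices are 0-based and
  only ever interpreted through a volume's spacing and origin. ROI floats
  are serialized with 9 significant digits so 3 mm threshold decisions
  survive a round-trip.
* Randomness flows from one master seed through string-keyed 31-bit child
  streams (`child_seed`), so each component (case, annotator, epoch,
  combination) is independently reproducible and insensitive to the
  execution order of its siblings.
* NIfTI-1 I/O is implemented in-package (no R NIfTI reader is available in
  the supported environment): single-file .nii/.nii.gz, float32 output,
  diagonal axis-aligned geometry only, explicit errors naming the
  offending header field otherwise.
* Default desk scales — 64-voxel phantoms, 16-voxel VOIs, ~20 epochs —
  keep one protocol arm in the seconds range; the published-scale values
  (32-voxel VOIs, 500/10 epochs) remain valid configuration.

## Known limitations

Phantoms are geometric, not anatomical; the linear baseline classifier
separates high-contrast phantom lesions far more easily than any real CAD
problem, so absolute CPM values are not meaningful — only comparisons
between arms of the same simulated study are. The annotator model is
memoryless across passes beyond the two-pass rule (no reader fatigue, no
inter-case learning). Soft-label fusion and consensus-panel (STAPLE-like)
integration are out of scope by design.
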