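---
title: "Hyperalignment and between-subject decoding: models, assumptions, and design choices"
author: "hyperalignR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperalignment and between-subject decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperalignR)
```

## The problem

Multivariate pattern analysis (MVPA) decodes experimental conditions from
multi-voxel fMRI activity patterns, but fine-scale voxel topographies are
idiosyncratic: a classifier trained on one subject transfers poorly to
another even after anatomical normalization to a template space.
Hyperalignment addresses this functionally rather than anatomically. Each
subject's data is treated as a trajectory in an n-dimensional voxel space,
and subjects are rotated into a shared high-dimensional *common model
space* by orthogonal Procrustes transformations, so that a single
subject-independent classifier becomes possible.

The package implements the full analysis around this idea for a
motor-imagery decoding design: a rich "session 1" time series from which
the common space and the per-subject transformations are derived, and a
"session 2" dataset of three imagined actions (lift, knock, throw) over
8 runs on which within-subject classification (WSC), between-subject
classification on anatomically aligned data (BSC-anat) and between-subject
classification after hyperalignment (BSC-hyper) are compared.

## The model

**Procrustes step.** For a source matrix $V$ (k timepoints x n voxels) and
a target $M$ of the same shape, the transformation is the orthogonal matrix
$T$ minimizing $\|VT - M\|_F$, obtained in closed form from the singular
value decomposition $V^\top M = U D W^\top$, $T = U W^\top$. Reflections
are permitted ($\det T = \pm 1$): the unconstrained orthogonal solution is
the exact minimizer, and permitting reflections preserves the testable
invariants (orthogonality, norm preservation). Translation is not fitted
because inputs are z-scored (centered); an optional single scalar gain can
be fitted (`allowScaling`), off by default. The mapping itself is
$M_{(k \times n)} = V_{(k \times n)} T_{(n \times n)}$.

**Three-stage common space.** `deriveCommonSpace()` follows the classical
iterative scheme. Stage 1: the first subject in the list is the reference;
each subsequent subject is aligned to the unweighted running mean of the
already-aligned subjects and then joins the mean. Stage 2: every subject's
original data is aligned to the stage-1 mean (the intermediate common
space) and the final common space is the average of these aligned spaces —
a single pass, deliberately not iterated to convergence. Stage 3: each
subject's transformation is re-derived by a fresh solve from its original
data to the final space. The intermediate mean is not re-normalized between
stage-1 steps. Because stage-3 transforms target the final space while the
final space was built from stage-2 alignments, the identity "final space =
mean of subjects mapped by their stored transforms" is exact only for
noiseless data; for noisy data it holds approximately.

Subjects enter stage 1 in list order, and the order is recorded: with
unequally reliable subjects the derived space genuinely depends on it,
which is what `runOrderSensitivity()` quantifies by re-deriving the model
under shuffled orders (2000 by default) and re-running BSC-hyper each time.

**Classifier.** A multiclass linear SVM as a set of binary classifiers,
one per unordered class pair, combined by majority voting. The binary
machines are libsvm fits (via e1071); the pairwise decomposition, the
negative-penalty convention and the vote resolution are implemented here.
A negative penalty `cRaw` requests automatic scaling: the effective C of a
binary subproblem is $|cRaw|$ divided by the mean squared Euclidean norm of
its training samples, an explicit operationalization of "scaling C to the
norm of the training data" (the historical implementation's exact formula
is not published; ours is documented rather than claimed identical). Vote
ties are broken by the largest summed signed decision value, then by class
order — deterministic and auditable.

**Cross-validation schemes.** WSC is leave-one-run-out within a subject
(8 runs x 3 block-averaged patterns: 8 folds, train 21 / test 3). BSC is
leave-one-subject-and-one-run-out: each fold trains on one run of the
other subjects and tests on the same run of the held-out subject
(10 subjects x 8 runs: 80 folds, train 27 / test 3). Training on the *same
run index* across subjects is a deliberate property of the scheme: it
matches train and test in session time. Per-subject BSC accuracy is the
mean over that subject's run folds, yielding one value per subject for the
repeated-measures ANOVA.

**Statistics.** Scenario accuracies are compared by a one-way
repeated-measures ANOVA with Greenhouse–Geisser correction (epsilon from
the double-centred condition covariance; both degrees of freedom
multiplied by epsilon) and Bonferroni-corrected pairwise paired t-tests.
Order-sensitivity permutations are compared against the fixed
anatomical-alignment baseline with a pooled two-sample t-test
(df = 2S − 2); the two-tailed critical value is computed from the t
distribution, never hard-coded. Box-whisker summaries use quartiles with
1.5 IQR whiskers.

## What the synthetic generator emulates

`generateStudy()` draws a shared latent representational space observed by
every subject through a subject-specific orthogonal voxel basis plus
i.i.d. Gaussian noise:

* **Session 1** (`session1Timepoints = 640`, scaled down from a
  1600-timepoint acquisition for desk-scale runtime; 25 condition patterns
  in latent dimension 25, mirroring a 25-condition blended-action design)
  is a condition block design with an added smooth sinusoidal component.
  The shared signal is centred and scaled to unit per-voxel standard
  deviation. Its per-timepoint noise (`session1NoiseSd = 1`, SNR near 1)
  is deliberately much lower than session 2's: the alignment session
  emulates a long, robust stimulation protocol, whereas pure motor imagery
  is weak per timepoint and relies on block averaging.
* **Session 2** is the labelled block design (3 classes x 8 runs x 3
  blocks per class per run, 16 s blocks and 8 s inter-block rest at
  TR = 2 s). Latent class means are drawn at scale `classSep = 1` and
  modulated per run by a *subject-shared* run effect
  (`runEffectSd = 1`): imagery vividness and attention drift over the
  session in a time-locked way, so a subject's patterns are less stable
  across runs than different subjects' patterns within the same run. This
  is the mechanism by which same-run between-subject training can beat a
  subject's own cross-run training, as the BSC fold design exploits.
* **Anatomical misalignment** (`anatMisalignment = 0.8`): each subject's
  orthogonal basis is the identity on a random 20% of voxel coordinates
  and a random orthogonal rotation on the remaining 80%. A permutation is
  itself orthogonal, so this construction subsumes voxel-identity
  scrambling while keeping an exact orthogonal alignment recoverable —
  anatomical-space correspondence is partial, hyperaligned correspondence
  is exact. Separate per-subject permutations of the scrambled subset are
  stored for `applyAnatMisalignment()`.
* **Noise calibration.** The default `noiseSd = 11` was calibrated once so
  that WSC lands mid-way in the 45–55% band (≈51% over replicates) at the
  default study size (10 subjects, 130 voxels — the size of a
  searchlight-selected region of interest). The other defaults were fixed
  before this calibration and not revisited.

What the generator does **not** model: hemodynamic convolution (labels are
shifted by 2 TRs = 4 s instead, which is exact for block designs), temporal
autocorrelation (block averages largely cancel it), scanner drift and
motion, and subject-specific idiosyncratic class geometry (all subjects
share the latent class means exactly). Passing tests therefore demonstrate
the correctness and calibration of the *analysis*, not that real motor
imagery data will reach these accuracies.

## Numerical choices and degenerate inputs

* Zero-variance voxels are a hard error in z-scoring (never silently
  dropped): voxel correspondence across subjects is the premise of the
  whole analysis.
* The hemodynamic label shift is applied within runs and never crosses run
  boundaries; annotations shifted past the end of a run are dropped.
* Procrustes requires at least two timepoints and a nonzero cross-product;
  unequal voxel counts across subjects are a hard error (no padding scheme
  is defined).
* With rank-deficient data (noiseless low-rank studies) the Procrustes
  solution is unique only up to the null space; recovery assertions are
  therefore made on mapped data and residuals, or on full-rank inputs.
* Noiseless recovery analyses run with `zscore = FALSE`: per-voxel
  z-scoring applies a subject-specific diagonal rescaling that breaks the
  exact orthogonal-image relation between noiseless subjects (the
  generator's output is already centred and unit-scale). Noisy analyses
  use the default per-run z-scoring.
* Searchlight spheres use Euclidean distance in voxel grid units, include
  the centre voxel, and are truncated at mask edges. ROI selection ranks
  voxels by searchlight accuracy (ties by ascending index) and returns the
  smallest candidate size within `tolerancePts` (default 1 percentage
  point) of the best candidate — an explicit version of "the number of
  voxels where accuracy reaches asymptote". The reference analysis'
  n = 130 voxels is a data-dependent outcome, not a constant.
* Where the z-scoring scope is not dictated (per run vs whole session),
  the default is per run — runs are independently acquired — and both are
  offered.

## Problem sizes used by the test-suite and acceptance script

The shipped checks run at deliberately chosen desk scales: the scenario
comparison and leave-one-subject-out generalization at the full default
study (10 subjects x 130 voxels) over seeded replicates; order-sensitivity
at 50 permutations (the reference configuration's 2000 remains the
function default); null calibration with 100 label permutations; and
noiseless recovery at 10 subjects x 60 voxels. All summaries the package
reports are recomputable from stored per-fold outputs, and seeded runs are
bit-reproducible.

## A worked example

```{r example, eval = FALSE}
study <- generateStudy(studyConfig(seed = 1))
comparison <- runComparison(study)
comparison
loo <- runLooGeneralization(study)
loo$meanAccuracy
```

At the default study conditions this prints per-scenario mean accuracies
near 0.51 (WSC), 0.35 (BSC-anat) and 0.65 (BSC-hyper), with the ANOVA
strongly rejecting equality — the qualitative signature the analysis is
designed to detect: hyperaligned between-subject decoding beats both
anatomical between-subject decoding and within-subject decoding.

## Known limitations

* The within-session hyperalignment variant derives transformations from
  the noisy classification session itself; at the default session-2 noise
  its accuracy sits far below the session-1-derived BSC-hyper (though
  above chance), while in the noiseless regime it is exact (100%). Real
  data with higher per-timepoint SNR sit between these regimes.
* Searchlight hyperalignment, connectivity hyperalignment and regularized
  (e.g. SVD-based) variants are out of scope.
* The generator's orthogonal-basis model is exactly the model class
  Procrustes can recover; it cannot probe model misspecification (e.g.
  non-orthogonal subject mappings).
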