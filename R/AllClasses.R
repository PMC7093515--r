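#' @import methods
#' @importFrom stats sd cov pf pt qt rnorm runif quantile t.test p.adjust
#' @importFrom utils combn read.table write.table packageVersion
NULL

## Central data containers. All matrices are dense base-R matrices:
## time series are timepoints x voxels, pattern sets are samples x voxels.

#' Study configuration for the synthetic multi-subject generator
#'
#' Describes a two-session multi-subject study: a rich "session 1" time
#' series used to derive hyperalignment parameters and a "session 2"
#' block-design classification dataset (default 3 motor-imagery classes,
#' lift / knock / throw, over 8 runs).
#'
#' @slot nSubjects number of subjects.
#' @slot nVoxels number of voxels per subject (shared across subjects).
#' @slot nLatentDims dimensionality of the shared latent representational
#'   space (must not exceed \code{nVoxels}).
#' @slot session1Timepoints number of session-1 timepoints (TRs).
#' @slot session1Conditions number of distinct session-1 condition patterns.
#' @slot nClasses number of session-2 stimulus classes.
#' @slot nRunsSession2 number of session-2 runs.
#' @slot blocksPerClassPerRun stimulus blocks per class within each run.
#' @slot blockLen block length in TRs.
#' @slot restLen inter-block interval in TRs.
#' @slot trSeconds repetition time in seconds.
#' @slot classSep standard deviation of latent class-mean coordinates
#'   (controls class separability).
#' @slot runEffectSd standard deviation of the run-specific modulation of
#'   the latent class patterns, shared across subjects (time-in-session
#'   drift of imagery vividness and attention). Makes a subject's patterns
#'   less stable across runs than across subjects within the same run.
#' @slot noiseSd additive Gaussian noise standard deviation for the
#'   session-2 (classification) data; a scalar or one value per subject.
#' @slot session1NoiseSd noise standard deviation for the session-1
#'   (alignment) data; scalar or per subject. Session 1 emulates a long,
#'   robust stimulation session, so its default is lower than the session-2
#'   level.
#' @slot anatMisalignment fraction in [0, 1] of voxels whose identity is
#'   scrambled across subjects in "anatomical" space.
#' @slot seed integer seed making generation reproducible.
#' @export
setClass("StudyConfig",
  representation(
    nSubjects = "numeric", nVoxels = "numeric", nLatentDims = "numeric",
    session1Timepoints = "numeric", session1Conditions = "numeric",
    nClasses = "numeric", nRunsSession2 = "numeric",
    blocksPerClassPerRun = "numeric", blockLen = "numeric",
    restLen = "numeric", trSeconds = "numeric", classSep = "numeric",
    runEffectSd = "numeric", noiseSd = "numeric",
    session1NoiseSd = "numeric",
    anatMisalignment = "numeric", seed = "numeric"))

setValidity("StudyConfig", function(object) {
  msgs <- character(0)
  count_fields <- c("nSubjects", "nVoxels", "nLatentDims",
                    "session1Timepoints", "session1Conditions", "nClasses",
                    "nRunsSession2", "blocksPerClassPerRun", "blockLen")
  for (f in count_fields) {
    v <- slot(object, f)
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v))
      msgs <- c(msgs, sprintf("'%s' must be a single integer >= 1", f))
  }
  if (length(object@restLen) != 1 || object@restLen < 0 ||
      object@restLen != round(object@restLen))
    msgs <- c(msgs, "'restLen' must be a single integer >= 0")
  if (length(msgs) == 0 && object@nLatentDims > object@nVoxels)
    msgs <- c(msgs, "'nLatentDims' must not exceed 'nVoxels'")
  if (any(!is.finite(object@noiseSd)) || any(object@noiseSd < 0))
    msgs <- c(msgs, "'noiseSd' must be nonnegative and finite")
  if (!(length(object@noiseSd) %in% c(1L, object@nSubjects)))
    msgs <- c(msgs, "'noiseSd' must be scalar or length nSubjects")
  if (any(!is.finite(object@session1NoiseSd)) ||
      any(object@session1NoiseSd < 0))
    msgs <- c(msgs, "'session1NoiseSd' must be nonnegative and finite")
  if (!(length(object@session1NoiseSd) %in% c(1L, object@nSubjects)))
    msgs <- c(msgs, "'session1NoiseSd' must be scalar or length nSubjects")
  if (length(object@anatMisalignment) != 1 ||
      object@anatMisalignment < 0 || object@anatMisalignment > 1)
    msgs <- c(msgs, "'anatMisalignment' must be a fraction in [0, 1]")
  if (length(object@trSeconds) != 1 || object@trSeconds <= 0)
    msgs <- c(msgs, "'trSeconds' must be a single positive number")
  if (length(object@classSep) != 1 || object@classSep < 0)
    msgs <- c(msgs, "'classSep' must be a single nonnegative number")
  if (length(object@runEffectSd) != 1 || object@runEffectSd < 0)
    msgs <- c(msgs, "'runEffectSd' must be a single nonnegative number")
  if (length(object@seed) != 1 || object@seed != round(object@seed))
    msgs <- c(msgs, "'seed' must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' One subject's masked, run-structured voxel time series
#'
#' Holds a timepoints x voxels response matrix together with per-timepoint
#' run labels and acquisition metadata. The \code{spaceTag} records whether
#' the columns live in the subject's (anatomically aligned) voxel space or
#' in the common model space.
#'
#' @slot data numeric matrix, timepoints x voxels.
#' @slot runIds integer run label per timepoint (rows of one run contiguous).
#' @slot trSeconds repetition time in seconds.
#' @slot subjectId subject identifier.
#' @slot spaceTag \code{"anatomical"} or \code{"common"}.
#' @export
setClass("VoxelTimeSeries",
  representation(data = "matrix", runIds = "integer", trSeconds = "numeric",
                 subjectId = "character", spaceTag = "character"))

setValidity("VoxelTimeSeries", function(object) {
  msgs <- character(0)
  if (!is.numeric(object@data)) msgs <- c(msgs, "'data' must be numeric")
  if (any(!is.finite(object@data)))
    msgs <- c(msgs, "'data' must contain only finite values")
  if (nrow(object@data) != length(object@runIds))
    msgs <- c(msgs, "length(runIds) must equal nrow(data)")
  r <- rle(object@runIds)$values
  if (anyDuplicated(r))
    msgs <- c(msgs, "'runIds' must partition rows into contiguous runs")
  if (!(object@spaceTag %in% c("anatomical", "common")))
    msgs <- c(msgs, "'spaceTag' must be 'anatomical' or 'common'")
  if (length(object@trSeconds) != 1 || object@trSeconds <= 0)
    msgs <- c(msgs, "'trSeconds' must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Block-averaged response patterns with class and run labels
#'
#' @slot patterns numeric matrix, samples x voxels (or common-space features).
#' @slot classLabels character class per sample.
#' @slot runIds integer run per sample.
#' @slot subjectId subject identifier.
#' @slot spaceTag \code{"anatomical"} or \code{"common"}.
#' @export
setClass("LabeledPatternSet",
  representation(patterns = "matrix", classLabels = "character",
                 runIds = "integer", subjectId = "character",
                 spaceTag = "character"))

setValidity("LabeledPatternSet", function(object) {
  msgs <- character(0)
  n <- nrow(object@patterns)
  if (length(object@classLabels) != n || length(object@runIds) != n)
    msgs <- c(msgs, "labels and runIds must have one entry per pattern row")
  if (any(!is.finite(object@patterns)))
    msgs <- c(msgs, "'patterns' must contain only finite values")
  if (!(object@spaceTag %in% c("anatomical", "common")))
    msgs <- c(msgs, "'spaceTag' must be 'anatomical' or 'common'")
  if (length(msgs)) msgs else TRUE
})

#' A subject's hyperalignment transformation
#'
#' The square matrix T mapping a subject's voxel space into the common model
#' space by right multiplication (mapped = data %*% T), optionally with a
#' single fitted scalar multiplier.
#'
#' @slot rotation n x n orthogonal matrix (rotation, possibly improper).
#' @slot scaling positive scalar multiplier (1 when scaling is disabled).
#' @slot sourceSubject identifier of the subject the transform maps from.
#' @export
setClass("OrthogonalTransform",
  representation(rotation = "matrix", scaling = "numeric",
                 sourceSubject = "character"))

setValidity("OrthogonalTransform", function(object) {
  msgs <- character(0)
  R <- object@rotation
  if (nrow(R) != ncol(R)) msgs <- c(msgs, "'rotation' must be square")
  else {
    dev <- sqrt(sum((crossprod(R) - diag(ncol(R)))^2))
    if (!is.finite(dev) || dev >= 1e-6)
      msgs <- c(msgs, sprintf(
        "'rotation' is not orthogonal (||T'T - I||_F = %.3g)", dev))
  }
  if (length(object@scaling) != 1 || object@scaling <= 0)
    msgs <- c(msgs, "'scaling' must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' The common model representational space
#'
#' Produced by the three-stage hyperalignment procedure: a stage-1 running
#' mean over subjects entered in order, a stage-2 average of all subjects
#' re-aligned to that intermediate space (the final common space), and
#' stage-3 per-subject transforms solved directly against the final space.
#'
#' @slot csFinal k x n final common space.
#' @slot csIntermediate k x n stage-1 intermediate common space (audit).
#' @slot transforms named list of \linkS4class{OrthogonalTransform}, one per
#'   contributing subject.
#' @slot subjectOrder subject identifiers in the order they entered stage 1.
#' @export
setClass("CommonModel",
  representation(csFinal = "matrix", csIntermediate = "matrix",
                 transforms = "list", subjectOrder = "character"))

setValidity("CommonModel", function(object) {
  msgs <- character(0)
  if (length(object@transforms) != length(object@subjectOrder))
    msgs <- c(msgs, "one transform per subject in 'subjectOrder' required")
  ok <- vapply(object@transforms, function(t)
    is(t, "OrthogonalTransform") && nrow(t@rotation) == ncol(object@csFinal),
    logical(1))
  if (!all(ok))
    msgs <- c(msgs, "transforms must match the common-space voxel dimension")
  if (!identical(dim(object@csFinal), dim(object@csIntermediate)))
    msgs <- c(msgs, "csFinal and csIntermediate must share dimensions")
  if (length(msgs)) msgs else TRUE
})

#' Cross-validated classification result
#'
#' @slot foldAccuracies accuracy per fold, in [0, 1].
#' @slot foldInfo data.frame describing each fold (held-out subject / run).
#' @slot meanAccuracy mean of the fold accuracies.
#' @slot standardError standard error of the fold accuracies.
#' @slot confusion class x class count matrix (rows true, columns predicted).
#' @slot schemeTag one of WSC, BSC_anat, BSC_hyper, BSC_hyper_loo.
#' @export
setClass("CVResult",
  representation(foldAccuracies = "numeric", foldInfo = "data.frame",
                 meanAccuracy = "numeric", standardError = "numeric",
                 confusion = "matrix", schemeTag = "character"))

setValidity("CVResult", function(object) {
  msgs <- character(0)
  if (any(object@foldAccuracies < 0 | object@foldAccuracies > 1))
    msgs <- c(msgs, "fold accuracies must lie in [0, 1]")
  if (abs(object@meanAccuracy - mean(object@foldAccuracies)) > 1e-12)
    msgs <- c(msgs, "meanAccuracy must equal mean(foldAccuracies)")
  if (nrow(object@confusion) != ncol(object@confusion))
    msgs <- c(msgs, "confusion matrix must be square")
  if (!(object@schemeTag %in%
        c("WSC", "BSC_anat", "BSC_hyper", "BSC_hyper_loo")))
    msgs <- c(msgs, "unknown schemeTag")
  if (length(msgs)) msgs else TRUE
})

#' Searchlight accuracy map
#'
#' @slot coords integer voxel grid coordinates (n x 3) of the mask voxels.
#' @slot accuracies decoding accuracy per mask voxel, in [0, 1].
#' @slot radiusVoxels searchlight sphere radius in voxel units.
#' @export
setClass("SearchlightMap",
  representation(coords = "matrix", accuracies = "numeric",
                 radiusVoxels = "numeric"))

setValidity("SearchlightMap", function(object) {
  msgs <- character(0)
  if (nrow(object@coords) != length(object@accuracies))
    msgs <- c(msgs, "one accuracy per mask voxel required")
  if (any(object@accuracies < 0 | object@accuracies > 1))
    msgs <- c(msgs, "accuracies must lie in [0, 1]")
  if (object@radiusVoxels < 0) msgs <- c(msgs, "radius must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' A generated synthetic study
#'
#' @slot config the \linkS4class{StudyConfig} used.
#' @slot session1 named list of session-1 \linkS4class{VoxelTimeSeries}.
#' @slot session2 named list of session-2 \linkS4class{VoxelTimeSeries}.
#' @slot labels data.frame (timepoint, run, block, class) describing the
#'   session-2 block design, shared across subjects; class is NA at rest.
#' @slot groundTruth list with the latent session-1 signal, latent class
#'   means, shared embedding, per-subject orthogonal bases, scrambled voxel
#'   subsets and anatomical permutations.
#' @export
setClass("SyntheticStudy",
  representation(config = "StudyConfig", session1 = "list",
                 session2 = "list", labels = "data.frame",
                 groundTruth = "list"))

#' Multiclass linear SVM specification
#'
#' One binary linear SVM per unordered class pair with majority voting.
#' A negative \code{cRaw} requests automatic scaling of the penalty:
#' effective C = |cRaw| / mean squared Euclidean norm of the training
#' samples of that binary subproblem.
#'
#' @slot kernel only \code{"linear"} is supported.
#' @slot cRaw raw penalty constant; negative triggers automatic scaling.
#' @slot classList optional fixed class order (inferred from training data
#'   when empty).
#' @export
setClass("ClassifierSpec",
  representation(kernel = "character", cRaw = "numeric",
                 classList = "character"))

setValidity("ClassifierSpec", function(object) {
  msgs <- character(0)
  if (!identical(object@kernel, "linear"))
    msgs <- c(msgs, "only the linear kernel is supported")
  if (length(object@cRaw) != 1 || !is.finite(object@cRaw) ||
      object@cRaw == 0)
    msgs <- c(msgs, "'cRaw' must be a single nonzero finite number")
  if (length(msgs)) msgs else TRUE
})

#' Scenario comparison result (WSC vs BSC-anat vs BSC-hyper)
#'
#' @slot accuracies subjects x scenarios matrix of per-subject accuracies.
#' @slot anova list with F, uncorrected and corrected dfs, p and the
#'   Greenhouse-Geisser epsilon of the repeated-measures ANOVA.
#' @slot pairwise data.frame of pairwise paired t-tests with the applied
#'   multiple-comparison correction.
#' @slot cvResults list of the underlying \linkS4class{CVResult} objects.
#' @export
setClass("ComparisonResult",
  representation(accuracies = "matrix", anova = "list",
                 pairwise = "data.frame", cvResults = "list"))

#' Subject-order permutation sensitivity result
#'
#' @slot permAccuracies mean hyperaligned BSC accuracy per permutation.
#' @slot orders list of subject orders, one per permutation.
#' @slot tTests data.frame with the per-permutation two-sample t statistic,
#'   df and p against the fixed anatomical-alignment baseline.
#' @slot summaryStats list with median, maximum, quartiles and 1.5 IQR
#'   whisker limits of the permutation accuracies.
#' @slot anatAccuracies per-subject anatomical-space BSC baseline.
#' @export
setClass("OrderSensitivityResult",
  representation(permAccuracies = "numeric", orders = "list",
                 tTests = "data.frame", summaryStats = "list",
                 anatAccuracies = "numeric"))
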