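#' @describeIn VoxelTimeSeries-class the timepoints x voxels matrix.
#' @param x object.
#' @aliases seriesData
#' @export
setMethod("seriesData", "VoxelTimeSeries", function(x) x@data)

#' @export
setMethod("runIds", "VoxelTimeSeries", function(x) x@runIds)
#' @export
setMethod("runIds", "LabeledPatternSet", function(x) x@runIds)
#' @export
setMethod("subjectId", "VoxelTimeSeries", function(x) x@subjectId)
#' @export
setMethod("subjectId", "LabeledPatternSet", function(x) x@subjectId)
#' @export
setMethod("spaceTag", "VoxelTimeSeries", function(x) x@spaceTag)
#' @export
setMethod("spaceTag", "LabeledPatternSet", function(x) x@spaceTag)
#' @export
setMethod("patterns", "LabeledPatternSet", function(x) x@patterns)
#' @export
setMethod("classLabels", "LabeledPatternSet", function(x) x@classLabels)
#' @export
setMethod("rotation", "OrthogonalTransform", function(x) x@rotation)
#' @export
setMethod("scalingFactor", "OrthogonalTransform", function(x) x@scaling)
#' @export
setMethod("csFinal", "CommonModel", function(x) x@csFinal)
#' @export
setMethod("csIntermediate", "CommonModel", function(x) x@csIntermediate)
#' @export
setMethod("transforms", "CommonModel", function(x) x@transforms)
#' @export
setMethod("subjectOrder", "CommonModel", function(x) x@subjectOrder)
#' @export
setMethod("foldAccuracies", "CVResult", function(x) x@foldAccuracies)
#' @export
setMethod("foldInfo", "CVResult", function(x) x@foldInfo)
#' @export
setMethod("meanAccuracy", "CVResult", function(x) x@meanAccuracy)
#' @export
setMethod("standardError", "CVResult", function(x) x@standardError)
#' @export
setMethod("confusion", "CVResult", function(x) x@confusion)
#' @export
setMethod("schemeTag", "CVResult", function(x) x@schemeTag)
#' @export
setMethod("accuracies", "SearchlightMap", function(x) x@accuracies)
#' @export
setMethod("accuracies", "ComparisonResult", function(x) x@accuracies)
#' @export
setMethod("accuracies", "OrderSensitivityResult", function(x) x@permAccuracies)
#' @export
setMethod("voxelCoords", "SearchlightMap", function(x) x@coords)
#' @export
setMethod("studyConfigOf", "SyntheticStudy", function(x) x@config)
#' @export
setMethod("session1", "SyntheticStudy", function(x) x@session1)
#' @export
setMethod("session2", "SyntheticStudy", function(x) x@session2)
#' @export
setMethod("studyLabels", "SyntheticStudy", function(x) x@labels)
#' @export
setMethod("groundTruth", "SyntheticStudy", function(x) x@groundTruth)

setMethod("show", "StudyConfig", function(object) {
  cat(sprintf(
    "StudyConfig: %d subjects, %d voxels (%d latent dims)\n",
    object@nSubjects, object@nVoxels, object@nLatentDims))
  cat(sprintf("  session 1: %d timepoints, %d conditions\n",
              object@session1Timepoints, object@session1Conditions))
  cat(sprintf(
    "  session 2: %d classes x %d runs, %d block(s)/class/run of %d TRs\n",
    object@nClasses, object@nRunsSession2, object@blocksPerClassPerRun,
    object@blockLen))
  cat(sprintf("  noiseSd: %s; anatMisalignment: %.2f; seed: %d\n",
              paste(format(object@noiseSd), collapse = ", "),
              object@anatMisalignment, as.integer(object@seed)))
})

setMethod("show", "VoxelTimeSeries", function(object) {
  cat(sprintf(
    "VoxelTimeSeries '%s' [%s space]: %d timepoints x %d voxels, %d run(s), TR %gs\n",
    object@subjectId, object@spaceTag, nrow(object@data), ncol(object@data),
    length(unique(object@runIds)), object@trSeconds))
})

setMethod("show", "LabeledPatternSet", function(object) {
  cat(sprintf(
    "LabeledPatternSet '%s' [%s space]: %d patterns x %d features; classes: %s\n",
    object@subjectId, object@spaceTag, nrow(object@patterns),
    ncol(object@patterns),
    paste(sort(unique(object@classLabels)), collapse = ", ")))
})

setMethod("show", "OrthogonalTransform", function(object) {
  cat(sprintf(
    "OrthogonalTransform from '%s': %d x %d (det %+.0f), scaling %g\n",
    object@sourceSubject, nrow(object@rotation), ncol(object@rotation),
    det(object@rotation), object@scaling))
})

setMethod("show", "CommonModel", function(object) {
  cat(sprintf("CommonModel: %d x %d common space from %d subjects\n",
              nrow(object@csFinal), ncol(object@csFinal),
              length(object@subjectOrder)))
  cat("  subject order:", paste(object@subjectOrder, collapse = " -> "), "\n")
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult [%s]: %d folds, mean accuracy %.3f (SE %.3f)\n",
              object@schemeTag, length(object@foldAccuracies),
              object@meanAccuracy, object@standardError))
})

setMethod("show", "SearchlightMap", function(object) {
  cat(sprintf(
    "SearchlightMap: %d voxels, radius %g; accuracy range [%.3f, %.3f]\n",
    length(object@accuracies), object@radiusVoxels,
    min(object@accuracies), max(object@accuracies)))
})

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy\n")
  show(object@config)
})

setMethod("show", "ComparisonResult", function(object) {
  cat("ComparisonResult (per-subject mean accuracies)\n")
  m <- colMeans(object@accuracies)
  for (i in seq_along(m))
    cat(sprintf("  %-13s %.3f\n", names(m)[i], m[i]))
  a <- object@anova
  cat(sprintf(
    "  rm-ANOVA (Greenhouse-Geisser): F(%.3f, %.3f) = %.3f, p = %.4g, eps = %.3f\n",
    a$df1Corrected, a$df2Corrected, a$F, a$p, a$epsilon))
})

setMethod("show", "OrderSensitivityResult", function(object) {
  s <- object@summaryStats
  cat(sprintf(
    "OrderSensitivityResult: %d permutations; median %.3f, max %.3f (IQR %.3f-%.3f)\n",
    length(object@permAccuracies), s$median, s$max, s$q1, s$q3))
})
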