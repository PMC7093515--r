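## Accessor generics. Slot access from user code should go through these.

#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))
#' @export
setGeneric("runIds", function(x) standardGeneric("runIds"))
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @export
setGeneric("spaceTag", function(x) standardGeneric("spaceTag"))
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @export
setGeneric("scalingFactor", function(x) standardGeneric("scalingFactor"))
#' @export
setGeneric("csFinal", function(x) standardGeneric("csFinal"))
#' @export
setGeneric("csIntermediate", function(x) standardGeneric("csIntermediate"))
#' @export
setGeneric("transforms", function(x) standardGeneric("transforms"))
#' @export
setGeneric("subjectOrder", function(x) standardGeneric("subjectOrder"))
#' @export
setGeneric("foldAccuracies", function(x) standardGeneric("foldAccuracies"))
#' @export
setGeneric("foldInfo", function(x) standardGeneric("foldInfo"))
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))
#' @export
setGeneric("standardError", function(x) standardGeneric("standardError"))
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))
#' @export
setGeneric("schemeTag", function(x) standardGeneric("schemeTag"))
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))
#' @export
setGeneric("voxelCoords", function(x) standardGeneric("voxelCoords"))
#' @export
setGeneric("studyConfigOf", function(x) standardGeneric("studyConfigOf"))
#' @export
setGeneric("session1", function(x) standardGeneric("session1"))
#' @export
setGeneric("session2", function(x) standardGeneric("session2"))
#' @export
setGeneric("studyLabels", function(x) standardGeneric("studyLabels"))
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Map data into the common model space
#'
#' Applies a subject's hyperalignment transformation by right multiplication
#' (Procrustes mapping): a k x n input with an n x n transform yields the
#' k x n mapped data, with labels, runs and subject identity preserved and
#' the space tag set to \code{"common"}.
#'
#' @param x a \linkS4class{VoxelTimeSeries} or \linkS4class{LabeledPatternSet}.
#' @param transform an \linkS4class{OrthogonalTransform}.
#' @return an object of the same class as \code{x} in common space.
#' @export
setGeneric("mapToCommon", function(x, transform) standardGeneric("mapToCommon"))
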