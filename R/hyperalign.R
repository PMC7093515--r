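#' Solve the orthogonal Procrustes problem
#'
#' Finds the orthogonal matrix T minimizing the Frobenius distance
#' ||source T - target||_F, the closed-form solution T = U V' obtained from
#' the singular value decomposition U D V' of source' target. Reflections
#' are permitted (det(T) may be -1); the unconstrained orthogonal solution
#' is the exact minimizer. With \code{allowScaling} a single positive scalar
#' multiplier is additionally fitted (s = sum(D) / ||source||_F^2).
#' Translation is not fitted: inputs are assumed centered (z-scored).
#'
#' @param source,target numeric k x n matrices of identical shape, k >= 2.
#' @param allowScaling fit a global scalar in addition to the rotation.
#' @param sourceSubject identifier stored on the returned transform.
#' @return an \linkS4class{OrthogonalTransform}.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' tf <- solveProcrustes(X, X)       # identity
#' @export
solveProcrustes <- function(source, target, allowScaling = FALSE,
                            sourceSubject = "source") {
  if (!is.matrix(source) || !is.matrix(target) ||
      !identical(dim(source), dim(target)))
    stop("'source' and 'target' must be matrices of identical shape")
  if (nrow(source) < 2)
    stop("at least two rows (timepoints) are required")
  M <- crossprod(source, target)
  if (!any(abs(M) > 0))
    stop("cross-product of source and target is zero; alignment undefined")
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  s <- if (allowScaling) sum(sv$d) / sum(source^2) else 1
  new("OrthogonalTransform", rotation = R, scaling = s,
      sourceSubject = sourceSubject)
}

procrustesResidual <- function(source, target, transform) {
  sqrt(sum((source %*% rotation(transform) * scalingFactor(transform) -
              target)^2))
}

asDataMatrix <- function(x) {
  if (is(x, "VoxelTimeSeries")) x@data
  else if (is(x, "LabeledPatternSet")) x@patterns
  else if (is.matrix(x)) x
  else stop("expected a VoxelTimeSeries, LabeledPatternSet or matrix")
}

#' Derive the common model space by three-stage hyperalignment
#'
#' Stage 1: the first subject of the list is the reference; each subsequent
#' subject is Procrustes-aligned to the unweighted running mean of the
#' already-aligned subjects and then enters the running mean. Stage 2: every
#' subject's original data is aligned to the stage-1 mean (the intermediate
#' common space) and the final common space is the mean of these aligned
#' spaces (a single pass, no iteration). Stage 3: each subject's
#' transformation is re-derived by a fresh Procrustes solve from its
#' original data to the final common space.
#'
#' The subject order of the input list is the order in which subjects enter
#' stage 1 and is recorded in the result; the derived space can depend on it
#' when subjects are unequally noisy.
#'
#' @param subjectData ordered list of \linkS4class{VoxelTimeSeries} (or bare
#'   matrices) sharing timepoint and voxel dimensions, already preprocessed.
#' @param allowScaling fit per-subject scalar multipliers.
#' @return a \linkS4class{CommonModel}.
#' @export
deriveCommonSpace <- function(subjectData, allowScaling = FALSE) {
  if (length(subjectData) < 1) stop("at least one subject is required")
  mats <- lapply(subjectData, asDataMatrix)
  ids <- names(subjectData)
  if (is.null(ids)) ids <- sprintf("sub%02d", seq_along(mats))
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all subjects must share timepoint and voxel dimensions")
  if (dims[1, 1] < 2) stop("at least two timepoints are required")
  S <- length(mats)

  ## stage 1: sequential alignment to the running mean
  runningMean <- mats[[1]]
  if (S > 1) {
    for (i in 2:S) {
      tf <- solveProcrustes(mats[[i]], runningMean, allowScaling, ids[i])
      aligned <- mats[[i]] %*% rotation(tf) * scalingFactor(tf)
      runningMean <- ((i - 1) * runningMean + aligned) / i
    }
  }
  csIntermediate <- runningMean

  ## stage 2: re-align everyone to the intermediate space, average
  aligned2 <- lapply(seq_len(S), function(i) {
    tf <- solveProcrustes(mats[[i]], csIntermediate, allowScaling, ids[i])
    mats[[i]] %*% rotation(tf) * scalingFactor(tf)
  })
  csFinal <- Reduce(`+`, aligned2) / S

  ## stage 3: fresh per-subject solves against the final space
  tfs <- lapply(seq_len(S), function(i)
    solveProcrustes(mats[[i]], csFinal, allowScaling, ids[i]))
  names(tfs) <- ids
  new("CommonModel", csFinal = csFinal, csIntermediate = csIntermediate,
      transforms = tfs, subjectOrder = ids)
}

#' @rdname mapToCommon
#' @export
setMethod("mapToCommon", signature("VoxelTimeSeries", "OrthogonalTransform"),
  function(x, transform) {
    if (ncol(x@data) != nrow(rotation(transform)))
      stop("voxel dimension of the data does not match the transform")
    x@data <- x@data %*% rotation(transform) * scalingFactor(transform)
    x@spaceTag <- "common"
    x
  })

#' @rdname mapToCommon
#' @export
setMethod("mapToCommon", signature("LabeledPatternSet", "OrthogonalTransform"),
  function(x, transform) {
    if (ncol(x@patterns) != nrow(rotation(transform)))
      stop("feature dimension of the patterns does not match the transform")
    x@patterns <- x@patterns %*% rotation(transform) * scalingFactor(transform)
    x@spaceTag <- "common"
    x
  })

#' Align a new subject to an existing common model
#'
#' Single Procrustes solve from the new subject's (preprocessed) time series
#' to the final common space of a model the subject did not contribute to.
#' The model is not modified. This supports leave-one-subject-out
#' generalization: a previously unseen subject can be mapped into a
#' pre-computed common space.
#'
#' @param model a \linkS4class{CommonModel}.
#' @param newData a \linkS4class{VoxelTimeSeries} (or matrix) sharing the
#'   model's timepoint and voxel dimensions.
#' @param allowScaling fit a scalar multiplier.
#' @return an \linkS4class{OrthogonalTransform} for the new subject.
#' @export
alignNewSubject <- function(model, newData, allowScaling = FALSE) {
  stopifnot(is(model, "CommonModel"))
  X <- asDataMatrix(newData)
  if (!identical(dim(X), dim(csFinal(model))))
    stop("new subject's data must share the common-space dimensions")
  id <- if (is(newData, "VoxelTimeSeries")) newData@subjectId else "new"
  solveProcrustes(X, csFinal(model), allowScaling, id)
}

#' Derive common models under permuted subject orders
#'
#' Draws seeded uniformly random subject orders (or enumerates all orders
#' exhaustively) and derives one common model per order, to probe the
#' sensitivity of the common space to the arbitrary reference-subject choice.
#'
#' @param subjectData named list of subject time series (or matrices).
#' @param nPerms number of permutations (2000 in the reference analysis).
#' @param seed integer seed for the permutation draw.
#' @param exhaustive enumerate all factorial(S) orders instead (ignores
#'   \code{nPerms}).
#' @param firstNatural force the first permutation to the natural order.
#' @param allowScaling fit per-subject scalar multipliers.
#' @return list with one element per order: \code{list(order, model)}.
#' @export
permuteSubjectOrders <- function(subjectData, nPerms = 2000, seed = 1,
                                 exhaustive = FALSE, firstNatural = FALSE,
                                 allowScaling = FALSE) {
  if (!exhaustive && nPerms < 1) stop("'nPerms' must be >= 1")
  S <- length(subjectData)
  ids <- names(subjectData)
  if (is.null(ids)) ids <- sprintf("sub%02d", seq_len(S))
  names(subjectData) <- ids
  orders <- if (exhaustive) {
    perms <- allPermutations(S)
    lapply(seq_len(nrow(perms)), function(i) perms[i, ])
  } else {
    withr::with_seed(as.integer(seed), {
      o <- replicate(nPerms, sample(S), simplify = FALSE)
      if (firstNatural) o[[1]] <- seq_len(S)
      o
    })
  }
  lapply(orders, function(o) {
    model <- deriveCommonSpace(subjectData[o], allowScaling)
    list(order = ids[o], model = model)
  })
}

allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
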