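#' Create a multiclass linear SVM specification
#'
#' The multiclass problem is translated into one binary linear SVM per
#' unordered class pair, combined by majority voting. A negative penalty
#' constant requests automatic scaling: the effective penalty of each binary
#' subproblem is |cRaw| divided by the mean squared Euclidean norm of its
#' training samples.
#'
#' @param cRaw raw penalty constant (default -1, i.e. automatic scaling).
#' @param classList optional fixed class order used for vote tie-breaking.
#' @return a \linkS4class{ClassifierSpec}.
#' @export
classifierSpec <- function(cRaw = -1, classList = character(0)) {
  new("ClassifierSpec", kernel = "linear", cRaw = cRaw,
      classList = classList)
}

effectivePenalty <- function(spec, x) {
  if (spec@cRaw > 0) return(spec@cRaw)
  abs(spec@cRaw) / mean(rowSums(x^2))
}

## Resolve pairwise votes into predicted classes. wins: samples x classes
## vote counts; scores: samples x classes summed signed decision values.
## Ties on votes are broken by the larger summed signed decision value, then
## by class order.
resolveVotes <- function(wins, scores, classes) {
  vapply(seq_len(nrow(wins)), function(i) {
    top <- which(wins[i, ] == max(wins[i, ]))
    if (length(top) > 1) {
      sc <- scores[i, top]
      top <- top[sc == max(sc)]
    }
    classes[top[1]]
  }, character(1))
}

#' Train pairwise linear SVMs and predict test patterns
#'
#' Trains one binary linear SVM per unordered class pair on the relevant
#' subset of the training patterns and predicts each test pattern by
#' majority vote over the pairwise decisions.
#'
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param train,test \linkS4class{LabeledPatternSet} objects with matching
#'   feature dimensions; every class must appear in \code{train}.
#' @return list with \code{predicted} (character labels), \code{votes}
#'   (samples x classes win counts) and \code{decisionValues} (samples x
#'   class pairs signed decision values, positive favouring the first class
#'   of the pair).
#' @export
trainPredict <- function(spec, train, test) {
  stopifnot(is(spec, "ClassifierSpec"), is(train, "LabeledPatternSet"),
            is(test, "LabeledPatternSet"))
  if (ncol(train@patterns) != ncol(test@patterns))
    stop("train and test feature dimensions differ")
  classes <- if (length(spec@classList)) spec@classList
             else sort(unique(train@classLabels))
  missing <- setdiff(classes, unique(train@classLabels))
  if (length(missing))
    stop("class missing from training data: ",
         paste(missing, collapse = ", "))
  pairs <- combn(classes, 2)
  nTest <- nrow(test@patterns)
  wins <- matrix(0L, nTest, length(classes),
                 dimnames = list(NULL, classes))
  scores <- matrix(0, nTest, length(classes),
                   dimnames = list(NULL, classes))
  dv <- matrix(NA_real_, nTest, ncol(pairs),
               dimnames = list(NULL, apply(pairs, 2, paste, collapse = "|")))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    rows <- train@classLabels %in% c(a, b)
    x <- train@patterns[rows, , drop = FALSE]
    y <- factor(train@classLabels[rows], levels = c(a, b))
    fit <- e1071::svm(x, y, kernel = "linear", scale = FALSE,
                      cost = effectivePenalty(spec, x))
    pr <- predict(fit, test@patterns, decision.values = TRUE)
    d <- attr(pr, "decision.values")[, 1]
    ## orient the decision value so that positive favours class a
    first <- strsplit(colnames(attr(pr, "decision.values"))[1], "/")[[1]][1]
    if (first != a) d <- -d
    dv[, j] <- d
    winA <- as.character(pr) == a
    wins[winA, a] <- wins[winA, a] + 1L
    wins[!winA, b] <- wins[!winA, b] + 1L
    scores[, a] <- scores[, a] + d
    scores[, b] <- scores[, b] - d
  }
  list(predicted = resolveVotes(wins, scores, classes), votes = wins,
       decisionValues = dv)
}

## Fold plans. Each fold is list(train = <sample rows or (subject, rows)>,
## test = ...). Kept as explicit enumerations so they can be checked by
## brute force.
wscFoldPlan <- function(runs) {
  uruns <- sort(unique(runs))
  lapply(uruns, function(r)
    list(run = r, train = which(runs != r), test = which(runs == r)))
}

bscFoldPlan <- function(subjects, runsPerSubject) {
  plan <- list()
  for (s in subjects) {
    for (r in sort(unique(runsPerSubject[[s]]))) {
      plan[[length(plan) + 1]] <- list(
        subject = s, run = r,
        trainSubjects = setdiff(subjects, s))
    }
  }
  plan
}

subsetPatterns <- function(ps, rows) {
  new("LabeledPatternSet", patterns = ps@patterns[rows, , drop = FALSE],
      classLabels = ps@classLabels[rows], runIds = ps@runIds[rows],
      subjectId = ps@subjectId, spaceTag = ps@spaceTag)
}

bindPatterns <- function(psList) {
  new("LabeledPatternSet",
      patterns = do.call(rbind, lapply(psList, function(p) p@patterns)),
      classLabels = unlist(lapply(psList, function(p) p@classLabels)),
      runIds = unlist(lapply(psList, function(p) p@runIds)),
      subjectId = "pooled", spaceTag = psList[[1]]@spaceTag)
}

newCVResult <- function(foldAcc, foldInfo, confusion, tag) {
  new("CVResult", foldAccuracies = foldAcc, foldInfo = foldInfo,
      meanAccuracy = mean(foldAcc),
      standardError = if (length(foldAcc) > 1)
        sd(foldAcc) / sqrt(length(foldAcc)) else 0,
      confusion = confusion, schemeTag = tag)
}

accumulateConfusion <- function(confusion, true, predicted) {
  for (i in seq_along(true))
    confusion[true[i], predicted[i]] <- confusion[true[i], predicted[i]] + 1
  confusion
}

#' Within-subject leave-one-run-out cross-validation
#'
#' One fold per run: the classifier is trained on all remaining runs of the
#' same subject and tested on the held-out run. With 8 runs of 3
#' block-averaged patterns this is an 8-fold cross-validation with 21
#' training and 3 test patterns per fold.
#'
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param subjectPatterns a \linkS4class{LabeledPatternSet} (>= 2 runs, every
#'   class present in every run).
#' @return a \linkS4class{CVResult} with scheme tag \code{"WSC"}.
#' @export
wscCV <- function(spec, subjectPatterns) {
  stopifnot(is(subjectPatterns, "LabeledPatternSet"))
  runs <- subjectPatterns@runIds
  if (length(unique(runs)) < 2) stop("at least two runs are required")
  classes <- if (length(spec@classList)) spec@classList
             else sort(unique(subjectPatterns@classLabels))
  for (r in unique(runs))
    if (!all(classes %in% subjectPatterns@classLabels[runs == r]))
      stop("run ", r, " is missing one or more classes")
  plan <- wscFoldPlan(runs)
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(classes, classes))
  acc <- numeric(length(plan))
  for (i in seq_along(plan)) {
    f <- plan[[i]]
    res <- trainPredict(spec, subsetPatterns(subjectPatterns, f$train),
                        subsetPatterns(subjectPatterns, f$test))
    truth <- subjectPatterns@classLabels[f$test]
    acc[i] <- mean(res$predicted == truth)
    conf <- accumulateConfusion(conf, truth, res$predicted)
  }
  newCVResult(acc, data.frame(subject = subjectPatterns@subjectId,
                              run = vapply(plan, `[[`, numeric(1), "run")),
              conf, "WSC")
}

#' Between-subject leave-one-subject-and-one-run-out cross-validation
#'
#' One fold per (held-out subject, held-out run) pair: the classifier is
#' trained on that run of all remaining subjects and tested on that run of
#' the held-out subject. With 10 subjects and 8 runs of 3 patterns this is
#' an 80-fold cross-validation with 27 training and 3 test patterns per
#' fold. All pattern sets must carry the requested space tag, preventing
#' accidental mixing of aligned and unaligned data.
#'
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param allPatterns named list of \linkS4class{LabeledPatternSet}, one per
#'   subject, with identical run structure and class sets.
#' @param space \code{"anatomical"} or \code{"common"}; every pattern set
#'   must carry this tag.
#' @return a \linkS4class{CVResult} tagged \code{"BSC_anat"} or
#'   \code{"BSC_hyper"}.
#' @export
bscCV <- function(spec, allPatterns, space = c("anatomical", "common")) {
  space <- match.arg(space)
  if (length(allPatterns) < 2) stop("at least two subjects are required")
  tags <- vapply(allPatterns, spaceTag, character(1))
  if (!all(tags == space))
    stop("space tag mismatch: expected all '", space, "', got: ",
         paste(unique(tags), collapse = ", "))
  ids <- names(allPatterns)
  if (is.null(ids))
    ids <- vapply(allPatterns, subjectId, character(1))
  names(allPatterns) <- ids
  classes <- if (length(spec@classList)) spec@classList
             else sort(unique(allPatterns[[1]]@classLabels))
  runsPerSubject <- lapply(allPatterns, function(p) p@runIds)
  plan <- bscFoldPlan(ids, runsPerSubject)
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(classes, classes))
  acc <- numeric(length(plan))
  for (i in seq_along(plan)) {
    f <- plan[[i]]
    train <- bindPatterns(lapply(allPatterns[f$trainSubjects], function(p)
      subsetPatterns(p, which(p@runIds == f$run))))
    testSet <- subsetPatterns(allPatterns[[f$subject]],
                              which(allPatterns[[f$subject]]@runIds == f$run))
    res <- trainPredict(spec, train, testSet)
    acc[i] <- mean(res$predicted == testSet@classLabels)
    conf <- accumulateConfusion(conf, testSet@classLabels, res$predicted)
  }
  newCVResult(acc,
              data.frame(subject = vapply(plan, `[[`, character(1), "subject"),
                         run = vapply(plan, `[[`, numeric(1), "run")),
              conf,
              if (space == "anatomical") "BSC_anat" else "BSC_hyper")
}

perSubjectAccuracy <- function(cv) {
  out <- tapply(cv@foldAccuracies, cv@foldInfo$subject, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Searchlight decoding map
#'
#' Assigns each mask voxel the cross-validated decoding accuracy obtained
#' from the features inside a sphere of the given radius centred on it
#' (Euclidean distance in voxel grid units, centre included, spheres
#' truncated at the mask edge). The within-subject scheme averages each
#' subject's leave-one-run-out accuracy across subjects; the between-subject
#' scheme runs leave-one-subject-and-one-run-out on the pooled subjects.
#'
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param allPatterns named list of per-subject
#'   \linkS4class{LabeledPatternSet} (a single set is accepted for WSC).
#' @param maskCoords integer matrix (voxels x 3) of grid coordinates, one
#'   row per pattern feature column.
#' @param radiusVoxels sphere radius in voxel units (3 in the reference
#'   analysis).
#' @param scheme \code{"WSC"} or \code{"BSC"}.
#' @return a \linkS4class{SearchlightMap}.
#' @export
searchlight <- function(spec, allPatterns, maskCoords, radiusVoxels = 3,
                        scheme = c("WSC", "BSC")) {
  scheme <- match.arg(scheme)
  if (is(allPatterns, "LabeledPatternSet")) allPatterns <- list(allPatterns)
  if (radiusVoxels < 0) stop("'radiusVoxels' must be >= 0")
  maskCoords <- as.matrix(maskCoords)
  nvox <- nrow(maskCoords)
  if (ncol(allPatterns[[1]]@patterns) != nvox)
    stop("one coordinate row per pattern feature is required")
  acc <- numeric(nvox)
  for (v in seq_len(nvox)) {
    d2 <- rowSums(sweep(maskCoords, 2, maskCoords[v, ], `-`)^2)
    nb <- which(d2 <= radiusVoxels^2 + 1e-9)
    sub <- lapply(allPatterns, function(p) {
      p@patterns <- p@patterns[, nb, drop = FALSE]; p
    })
    acc[v] <- if (scheme == "WSC")
      mean(vapply(sub, function(p) meanAccuracy(wscCV(spec, p)), numeric(1)))
    else
      meanAccuracy(bscCV(spec, sub, space = sub[[1]]@spaceTag))
  }
  new("SearchlightMap", coords = maskCoords, accuracies = acc,
      radiusVoxels = radiusVoxels)
}

#' Select a region of interest at the accuracy asymptote
#'
#' Ranks voxels by searchlight accuracy (ties broken by ascending voxel
#' index), evaluates the cross-validated accuracy of the top-N voxel sets
#' over the candidate sizes, and returns the indices of the smallest N whose
#' accuracy is within \code{tolerancePts} percentage points of the best
#' candidate -- the point where accuracy has reached its asymptote.
#'
#' @param map a \linkS4class{SearchlightMap}.
#' @param allPatterns per-subject pattern list (BSC evaluation) or a single
#'   \linkS4class{LabeledPatternSet} (WSC evaluation).
#' @param candidateSizes ascending candidate voxel counts.
#' @param tolerancePts asymptote tolerance in percentage points (default 1).
#' @param spec a \linkS4class{ClassifierSpec}.
#' @return integer vector of the selected voxel indices (attribute
#'   \code{"sizeAccuracies"} carries the candidate accuracy profile).
#' @export
selectROI <- function(map, allPatterns, candidateSizes, tolerancePts = 1,
                      spec = classifierSpec()) {
  if (length(candidateSizes) == 0) stop("'candidateSizes' must be non-empty")
  if (is.unsorted(candidateSizes))
    stop("'candidateSizes' must be sorted ascending")
  ranking <- order(-map@accuracies, seq_along(map@accuracies))
  single <- is(allPatterns, "LabeledPatternSet")
  accs <- vapply(candidateSizes, function(N) {
    keep <- ranking[seq_len(N)]
    if (single) {
      p <- allPatterns; p@patterns <- p@patterns[, keep, drop = FALSE]
      meanAccuracy(wscCV(spec, p))
    } else {
      sub <- lapply(allPatterns, function(p) {
        p@patterns <- p@patterns[, keep, drop = FALSE]; p
      })
      meanAccuracy(bscCV(spec, sub, space = sub[[1]]@spaceTag))
    }
  }, numeric(1))
  best <- max(accs)
  N <- candidateSizes[which(accs >= best - tolerancePts / 100)[1]]
  out <- ranking[seq_len(N)]
  attr(out, "sizeAccuracies") <- data.frame(size = candidateSizes,
                                            accuracy = accs)
  out
}
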