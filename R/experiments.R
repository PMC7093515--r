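#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical subjects x conditions decomposition: F is the ratio of the
#' condition mean square to the subject-by-condition interaction mean
#' square. The Greenhouse-Geisser epsilon is computed from the
#' double-centred condition covariance matrix and is used to correct both
#' degrees of freedom before evaluating the p value. When the conditions
#' are identical (zero condition and error sums of squares) F is reported
#' as 0 with p = 1.
#'
#' @param Y numeric subjects x conditions matrix.
#' @return list with \code{F}, uncorrected dfs, Greenhouse-Geisser
#'   \code{epsilon}, corrected dfs and \code{p}.
#' @export
repeatedMeasuresAnova <- function(Y) {
  Y <- as.matrix(Y)
  S <- nrow(Y); m <- ncol(Y)
  if (S < 2 || m < 2) stop("need at least 2 subjects and 2 conditions")
  grand <- mean(Y)
  ssCond <- S * sum((colMeans(Y) - grand)^2)
  ssSubj <- m * sum((rowMeans(Y) - grand)^2)
  ssErr <- sum((Y - grand)^2) - ssCond - ssSubj
  dfC <- m - 1; dfE <- (m - 1) * (S - 1)
  Sig <- cov(Y)
  J <- diag(m) - 1 / m
  Sc <- J %*% Sig %*% J
  denom <- (m - 1) * sum(Sc * Sc)
  eps <- if (denom > 0) sum(diag(Sc))^2 / denom else 1
  eps <- min(max(eps, 1 / (m - 1)), 1)
  if (ssCond < 1e-24 && ssErr < 1e-24) {
    Fv <- 0; p <- 1
  } else if (ssErr <= 0) {
    Fv <- Inf; p <- 0
  } else {
    Fv <- (ssCond / dfC) / (ssErr / dfE)
    p <- pf(Fv, eps * dfC, eps * dfE, lower.tail = FALSE)
  }
  list(F = Fv, df1 = dfC, df2 = dfE, epsilon = eps,
       df1Corrected = eps * dfC, df2Corrected = eps * dfE, p = p)
}

pairwisePairedTests <- function(Y, method = "bonferroni") {
  cn <- colnames(Y)
  pairs <- combn(ncol(Y), 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- Y[, a] - Y[, b]
    if (sd(d) < 1e-15) {
      tt <- list(statistic = 0, parameter = length(d) - 1,
                 p.value = if (abs(mean(d)) < 1e-15) 1 else 0)
    } else tt <- t.test(Y[, a], Y[, b], paired = TRUE)
    data.frame(a = cn[a], b = cn[b], meanDiff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$pAdjusted <- p.adjust(out$p, method = method)
  out$correction <- method
  out
}

## Two-sample pooled-variance t-test (df = nx + ny - 2) with a defined
## value for the degenerate equal-constant case.
twoSampleT <- function(x, y) {
  df <- length(x) + length(y) - 2
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  if (sp2 < 1e-30) {
    t <- if (abs(mean(x) - mean(y)) < 1e-15) 0 else
      sign(mean(x) - mean(y)) * Inf
  } else {
    t <- (mean(x) - mean(y)) /
      sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  }
  list(t = t, df = df, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

## Preprocess session-2 series into block-averaged anatomical-space
## patterns: optional per-run z-scoring, hemodynamic label shift, block
## averaging.
sessionPatterns <- function(study, zscore = TRUE, shiftTrs = 2,
                            scope = "per_run") {
  labs <- shiftForHemodynamics(studyLabels(study), shiftTrs)
  lapply(session2(study), function(ts) {
    if (zscore) ts <- zscoreTimeSeries(ts, scope)
    averageBlocks(ts, labs)
  })
}

prepSession1 <- function(study, zscore = TRUE, scope = "per_run") {
  lapply(session1(study), function(ts)
    if (zscore) zscoreTimeSeries(ts, scope) else ts)
}

#' Compare WSC, anatomical BSC and hyperaligned BSC
#'
#' Runs the three classification scenarios on a study's session-2 data:
#' within-subject leave-one-run-out classification, between-subject
#' classification on anatomically aligned patterns, and between-subject
#' classification after mapping each subject's patterns into the common
#' model space. Per-subject accuracies (the mean over each subject's
#' held-out folds) are compared by a repeated-measures ANOVA with
#' Greenhouse-Geisser correction and Bonferroni-corrected pairwise paired
#' t-tests.
#'
#' @param study a \linkS4class{SyntheticStudy} (or compatible object).
#' @param model a \linkS4class{CommonModel} derived from the same subjects'
#'   session-1 data; derived automatically when \code{NULL}.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param zscore z-score the series per run before block averaging.
#' @param shiftTrs hemodynamic label shift in TRs.
#' @return a \linkS4class{ComparisonResult}.
#' @export
runComparison <- function(study, model = NULL, spec = classifierSpec(),
                          zscore = TRUE, shiftTrs = 2) {
  if (is.null(model))
    model <- deriveCommonSpace(prepSession1(study, zscore))
  if (!setequal(subjectOrder(model), names(session2(study))))
    stop("model subjects do not match the study subjects")
  anatPatterns <- sessionPatterns(study, zscore, shiftTrs)
  hyperPatterns <- lapply(names(anatPatterns), function(id)
    mapToCommon(anatPatterns[[id]], transforms(model)[[id]]))
  names(hyperPatterns) <- names(anatPatterns)

  wscResults <- lapply(anatPatterns, function(p) wscCV(spec, p))
  bscAnat <- bscCV(spec, anatPatterns, space = "anatomical")
  bscHyper <- bscCV(spec, hyperPatterns, space = "common")

  ids <- names(anatPatterns)
  Y <- cbind(WSC = vapply(wscResults, meanAccuracy, numeric(1)),
             BSC_anat = perSubjectAccuracy(bscAnat)[ids],
             BSC_hyper = perSubjectAccuracy(bscHyper)[ids])
  rownames(Y) <- ids
  new("ComparisonResult", accuracies = Y,
      anova = repeatedMeasuresAnova(Y),
      pairwise = pairwisePairedTests(Y),
      cvResults = list(WSC = wscResults, BSC_anat = bscAnat,
                       BSC_hyper = bscHyper))
}

#' Sensitivity of the common model space to subject order
#'
#' Re-derives the common model space under shuffled subject orders (2000 in
#' the reference analysis), maps the session-2 patterns under each model,
#' and records the hyperaligned BSC accuracy per permutation together with
#' a two-sample two-tailed t-test (df = 2S - 2) of the per-subject
#' accuracies against the fixed anatomical-alignment baseline. The summary
#' uses quartiles with 1.5 IQR whiskers.
#'
#' @param study a \linkS4class{SyntheticStudy}.
#' @param nPerms number of subject-order permutations.
#' @param seed integer seed for the permutation draw.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param zscore,shiftTrs preprocessing options, as in
#'   \code{\link{runComparison}}.
#' @return an \linkS4class{OrderSensitivityResult}.
#' @export
runOrderSensitivity <- function(study, nPerms = 2000, seed = 1,
                                spec = classifierSpec(), zscore = TRUE,
                                shiftTrs = 2) {
  if (nPerms < 2) stop("'nPerms' must be >= 2")
  anatPatterns <- sessionPatterns(study, zscore, shiftTrs)
  anatPerSubject <- perSubjectAccuracy(
    bscCV(spec, anatPatterns, space = "anatomical"))
  prep1 <- prepSession1(study, zscore)
  permModels <- permuteSubjectOrders(prep1, nPerms = nPerms, seed = seed)
  ids <- names(anatPatterns)
  permAcc <- numeric(length(permModels))
  tRows <- vector("list", length(permModels))
  orders <- vector("list", length(permModels))
  for (i in seq_along(permModels)) {
    model <- permModels[[i]]$model
    hyper <- lapply(ids, function(id)
      mapToCommon(anatPatterns[[id]], transforms(model)[[id]]))
    names(hyper) <- ids
    cv <- bscCV(spec, hyper, space = "common")
    permAcc[i] <- meanAccuracy(cv)
    tt <- twoSampleT(perSubjectAccuracy(cv)[ids], anatPerSubject[ids])
    tRows[[i]] <- data.frame(perm = i, t = tt$t, df = tt$df, p = tt$p)
    orders[[i]] <- permModels[[i]]$order
  }
  q <- unname(quantile(permAcc, c(0.25, 0.5, 0.75)))
  iqr <- q[3] - q[1]
  summaryStats <- list(
    median = q[2], max = max(permAcc), min = min(permAcc),
    q1 = q[1], q3 = q[3],
    whiskerLow = min(permAcc[permAcc >= q[1] - 1.5 * iqr]),
    whiskerHigh = max(permAcc[permAcc <= q[3] + 1.5 * iqr]))
  new("OrderSensitivityResult", permAccuracies = permAcc, orders = orders,
      tTests = do.call(rbind, tRows), summaryStats = summaryStats,
      anatAccuracies = anatPerSubject[ids])
}

#' Within-session hyperalignment and classification
#'
#' Derives the common space from the session-2 time series itself, one
#' held-out run at a time: for each run r the common model is computed from
#' all subjects' data excluding run r, run r of every subject is mapped
#' into that space, and the classifier is trained on the mapped run-r
#' patterns of all subjects but one and tested on the held-out subject's
#' mapped run-r patterns. The test data therefore contribute neither to the
#' alignment nor to classifier training.
#'
#' @param study a \linkS4class{SyntheticStudy}.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param zscore,shiftTrs preprocessing options.
#' @return a \linkS4class{CVResult} (one fold per subject x run pair).
#' @export
runWithinSessionHyperalignment <- function(study, spec = classifierSpec(),
                                           zscore = TRUE, shiftTrs = 2) {
  series <- lapply(session2(study), function(ts)
    if (zscore) zscoreTimeSeries(ts, "per_run") else ts)
  ids <- names(series)
  if (length(ids) < 2) stop("at least two subjects are required")
  labs <- shiftForHemodynamics(studyLabels(study), shiftTrs)
  runs <- sort(unique(runIds(series[[1]])))
  if (length(runs) < 2) stop("at least two runs are required")
  classes <- sort(unique(labs$class[!is.na(labs$class)]))
  conf <- matrix(0, length(classes), length(classes),
                 dimnames = list(classes, classes))
  acc <- numeric(0); info <- list()
  for (r in runs) {
    trainMats <- lapply(series, function(ts)
      seriesData(ts)[runIds(ts) != r, , drop = FALSE])
    model <- deriveCommonSpace(trainMats)
    ## block-average the held-out run and map it for every subject
    mapped <- lapply(ids, function(id) {
      ts <- series[[id]]
      keep <- runIds(ts) == r
      sub <- new("VoxelTimeSeries", data = seriesData(ts)[keep, , drop = FALSE],
                 runIds = runIds(ts)[keep], trSeconds = ts@trSeconds,
                 subjectId = id, spaceTag = "anatomical")
      pats <- averageBlocks(sub, labs[keep, , drop = FALSE])
      mapToCommon(pats, transforms(model)[[id]])
    })
    names(mapped) <- ids
    for (s in ids) {
      train <- bindPatterns(mapped[setdiff(ids, s)])
      res <- trainPredict(spec, train, mapped[[s]])
      truth <- mapped[[s]]@classLabels
      acc <- c(acc, mean(res$predicted == truth))
      conf <- accumulateConfusion(conf, truth, res$predicted)
      info[[length(info) + 1]] <- data.frame(subject = s, run = r)
    }
  }
  newCVResult(acc, do.call(rbind, info), conf, "BSC_hyper")
}

#' Leave-one-subject-out generalization of the common model
#'
#' For each subject s the common model is derived from the other subjects'
#' session-1 data, subject s is aligned to that model by a single Procrustes
#' solve on its own session-1 data, and between-subject classification
#' trains on the contributors' mapped session-2 patterns (run-wise, as in
#' \code{\link{bscCV}}) and tests on the newly mapped subject's patterns.
#'
#' @param study a \linkS4class{SyntheticStudy} with >= 3 subjects.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param zscore,shiftTrs preprocessing options.
#' @return list with \code{perSubject} (one \linkS4class{CVResult} per
#'   left-out subject, tag \code{"BSC_hyper_loo"}), \code{subjectAccuracies},
#'   \code{meanAccuracy} and \code{standardError} (over subjects).
#' @export
runLooGeneralization <- function(study, spec = classifierSpec(),
                                 zscore = TRUE, shiftTrs = 2) {
  prep1 <- prepSession1(study, zscore)
  ids <- names(prep1)
  if (length(ids) < 3) stop("at least three subjects are required")
  anatPatterns <- sessionPatterns(study, zscore, shiftTrs)
  classes <- sort(unique(anatPatterns[[1]]@classLabels))
  perSubject <- list()
  for (s in ids) {
    contributors <- setdiff(ids, s)
    model <- deriveCommonSpace(prep1[contributors])
    tLoo <- alignNewSubject(model, prep1[[s]])
    mapped <- lapply(contributors, function(id)
      mapToCommon(anatPatterns[[id]], transforms(model)[[id]]))
    names(mapped) <- contributors
    mappedLoo <- mapToCommon(anatPatterns[[s]], tLoo)
    conf <- matrix(0, length(classes), length(classes),
                   dimnames = list(classes, classes))
    runs <- sort(unique(mappedLoo@runIds))
    acc <- numeric(0); info <- list()
    for (r in runs) {
      train <- bindPatterns(lapply(mapped, function(p)
        subsetPatterns(p, which(p@runIds == r))))
      testSet <- subsetPatterns(mappedLoo, which(mappedLoo@runIds == r))
      res <- trainPredict(spec, train, testSet)
      acc <- c(acc, mean(res$predicted == testSet@classLabels))
      conf <- accumulateConfusion(conf, testSet@classLabels, res$predicted)
      info[[length(info) + 1]] <- data.frame(subject = s, run = r)
    }
    perSubject[[s]] <- newCVResult(acc, do.call(rbind, info), conf,
                                   "BSC_hyper_loo")
  }
  subjectAcc <- vapply(perSubject, meanAccuracy, numeric(1))
  list(perSubject = perSubject, subjectAccuracies = subjectAcc,
       meanAccuracy = mean(subjectAcc),
       standardError = sd(subjectAcc) / sqrt(length(subjectAcc)))
}
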