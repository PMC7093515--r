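test_that("pairwise majority voting predicts unanimous and 2-class cases", {
  train <- makePatterns(nRuns = 2)
  test <- makePatterns(nRuns = 1, seed = 2)
  res <- trainPredict(classifierSpec(), train, test)
  expect_equal(res$predicted, classLabels(test))
  expect_equal(ncol(res$decisionValues), 3)    # one per class pair
  # every sample's winning class collected all its pairwise votes
  expect_true(all(apply(res$votes, 1, max) == 2))

  # two classes: a single binary classifier decides
  keep <- classLabels(train) %in% c("A", "B")
  train2 <- hyperalignR:::subsetPatterns(train, which(keep))
  test2 <- hyperalignR:::subsetPatterns(test,
                                        which(classLabels(test) != "C"))
  res2 <- trainPredict(classifierSpec(), train2, test2)
  expect_equal(ncol(res2$decisionValues), 1)
  expect_equal(res2$predicted, classLabels(test2))
  expect_error(trainPredict(classifierSpec(), train2, test), NA)
  expect_error(
    trainPredict(classifierSpec(classList = c("A", "B", "C")), train2, test),
    "missing")
})

test_that("cyclic vote ties resolve by summed decision value, then order", {
  # brute force over every signed outcome of the three pairwise duels
  classes <- c("A", "B", "C")
  pairs <- combn(classes, 2)
  for (bits in 0:7) {
    signs <- ifelse(bitwAnd(bits, 2^(0:2)) > 0, 1, -1)
    mags <- c(0.6, 0.5, 0.4)
    wins <- matrix(0L, 1, 3, dimnames = list(NULL, classes))
    scores <- matrix(0, 1, 3, dimnames = list(NULL, classes))
    for (j in 1:3) {
      a <- pairs[1, j]; b <- pairs[2, j]
      d <- signs[j] * mags[j]
      if (d > 0) wins[1, a] <- wins[1, a] + 1L
      else wins[1, b] <- wins[1, b] + 1L
      scores[1, a] <- scores[1, a] + d
      scores[1, b] <- scores[1, b] - d
    }
    got <- hyperalignR:::resolveVotes(wins, scores, classes)
    # independent enumeration of the expected winner
    top <- which(wins[1, ] == max(wins[1, ]))
    if (length(top) > 1) top <- top[scores[1, top] == max(scores[1, top])]
    expect_identical(got, classes[top[1]])
  }
})

test_that("negative C scales the penalty by the mean squared sample norm", {
  spec <- classifierSpec(cRaw = -2)
  x <- rbind(c(3, 4), c(0, 2))            # norms^2: 25, 4 -> mean 14.5
  expect_equal(hyperalignR:::effectivePenalty(spec, x), 2 / 14.5)
  expect_equal(hyperalignR:::effectivePenalty(classifierSpec(cRaw = 5), x), 5)
  expect_error(classifierSpec(cRaw = 0), "nonzero")
})

test_that("leave-one-run-out folds enumerate the run structure", {
  ps <- makePatterns(nRuns = 8, nClasses = 3, nVoxels = 5, jitter = 0.1)
  cv <- wscCV(classifierSpec(), ps)
  expect_equal(length(foldAccuracies(cv)), 8)
  expect_equal(foldInfo(cv)$run, 1:8)
  plan <- hyperalignR:::wscFoldPlan(runIds(ps))
  for (f in plan) {
    expect_equal(length(f$train), 21)
    expect_equal(length(f$test), 3)
    # brute-force check of the index split
    expect_identical(sort(c(f$train, f$test)), seq_len(24))
    expect_true(all(runIds(ps)[f$test] == f$run))
    expect_true(all(runIds(ps)[f$train] != f$run))
  }
  expect_equal(sum(confusion(cv)), 24)    # folds x test size
  expect_equal(unname(rowSums(confusion(cv))), rep(8, 3))
  # separable noiseless classes decode perfectly
  expect_equal(meanAccuracy(wscCV(classifierSpec(),
                                  makePatterns(nRuns = 4))), 1)
  oneRun <- hyperalignR:::subsetPatterns(ps, 1:3)
  expect_error(wscCV(classifierSpec(), oneRun), "two runs")
})

test_that("leave-one-subject-and-one-run-out folds cover subject x run", {
  sets <- lapply(sprintf("sub%02d", 1:10), function(id)
    makePatterns(nRuns = 8, nVoxels = 4, jitter = 0.3, subjectId = id,
                 seed = match(id, sprintf("sub%02d", 1:10))))
  names(sets) <- sprintf("sub%02d", 1:10)
  cv <- bscCV(classifierSpec(), sets, space = "anatomical")
  expect_equal(length(foldAccuracies(cv)), 80)
  expect_equal(nrow(unique(foldInfo(cv))), 80)
  expect_equal(sum(confusion(cv)), 240)
  plan <- hyperalignR:::bscFoldPlan(names(sets),
                                    lapply(sets, runIds))
  expect_equal(length(plan), 80)
  for (f in plan[c(1, 40, 80)]) {
    expect_equal(length(f$trainSubjects), 9)
    expect_false(f$subject %in% f$trainSubjects)
  }
  # training set per fold: 1 run x 9 subjects x 3 classes = 27 patterns
  f <- plan[[1]]
  trainRows <- sum(vapply(sets[f$trainSubjects], function(p)
    sum(runIds(p) == f$run), integer(1)))
  expect_equal(trainRows, 27)
  # identical separable subjects decode perfectly
  same <- lapply(sprintf("s%d", 1:3), function(id)
    makePatterns(nRuns = 3, subjectId = id, seed = 1))
  names(same) <- sprintf("s%d", 1:3)
  expect_equal(meanAccuracy(bscCV(classifierSpec(), same, "anatomical")), 1)
  # space-tag mixing is refused
  same[[1]]@spaceTag <- "common"
  expect_error(bscCV(classifierSpec(), same, "anatomical"), "space tag")
})

test_that("accuracy is invariant under a common orthogonal rotation", {
  ps <- makePatterns(nRuns = 6, nVoxels = 8, jitter = 1.2, seed = 4)
  Q <- randomOrtho(8, seed = 6)
  rot <- ps; rot@patterns <- ps@patterns %*% Q
  a <- wscCV(classifierSpec(), ps)
  b <- wscCV(classifierSpec(), rot)
  expect_equal(foldAccuracies(a), foldAccuracies(b), tolerance = 1e-9)
})

test_that("searchlight spheres honor the radius and recover information", {
  coords <- as.matrix(expand.grid(x = 1:3, y = 1:3, z = 1))
  ps <- makePatterns(nRuns = 4, nVoxels = 9, jitter = 0.8, seed = 3)
  sl0 <- searchlight(classifierSpec(), ps, coords, radiusVoxels = 0,
                     scheme = "WSC")
  # radius 0: each voxel classified alone
  for (v in c(1, 5, 9)) {
    solo <- ps; solo@patterns <- ps@patterns[, v, drop = FALSE]
    expect_equal(accuracies(sl0)[v], meanAccuracy(wscCV(classifierSpec(),
                                                        solo)))
  }
  big <- searchlight(classifierSpec(), ps, coords, radiusVoxels = 10,
                     scheme = "WSC")
  # radius covering the whole mask: every sphere is the full pattern
  expect_equal(accuracies(big),
               rep(meanAccuracy(wscCV(classifierSpec(), ps)), 9))
})

test_that("ROI selection returns the smallest candidate at the asymptote", {
  # informative voxels 1:2 (class signal), uninformative 3:6
  classes <- rep(LETTERS[1:3], 6)
  runs <- rep(1:6, each = 3)
  signal <- diag(3)[match(classes, LETTERS[1:3]), ] * 2.5
  withr::with_seed(8, {
    pats <- cbind(signal[, 1], signal[, 2],
                  matrix(rnorm(18 * 4), 18, 4)) +
      matrix(rnorm(18 * 6, sd = 0.3), 18, 6)
  })
  ps <- new("LabeledPatternSet", patterns = pats, classLabels = classes,
            runIds = as.integer(runs), subjectId = "s", spaceTag = "anatomical")
  map <- new("SearchlightMap", coords = cbind(1:6, 1, 1),
             accuracies = c(0.9, 0.8, 0.4, 0.3, 0.3, 0.3),
             radiusVoxels = 0)
  roi <- selectROI(map, ps, candidateSizes = c(1, 2, 4, 6))
  prof <- attr(roi, "sizeAccuracies")
  # independent scan: smallest N within 1 point of the best accuracy
  best <- max(prof$accuracy)
  expectN <- prof$size[which(prof$accuracy >= best - 0.01)[1]]
  expect_equal(length(roi), expectN)
  expect_identical(roi[1], 1L)             # ranked by map accuracy
  # equal accuracies everywhere -> smallest candidate
  flat <- map; flat@accuracies <- rep(0.5, 6)
  psSame <- makePatterns(nRuns = 4, nVoxels = 6)
  roiFlat <- selectROI(flat, psSame, candidateSizes = c(2, 4, 6))
  expect_equal(length(roiFlat), 2)
  expect_error(selectROI(map, ps, candidateSizes = integer(0)), "non-empty")
  expect_error(selectROI(map, ps, candidateSizes = c(4, 2)), "ascending")
})
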