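test_that("repeated-measures ANOVA matches a brute-force SS decomposition", {
  withr::with_seed(21, {
    Y <- matrix(runif(15, 0.3, 0.9), 5, 3,
                dimnames = list(NULL, c("c1", "c2", "c3")))
  })
  res <- repeatedMeasuresAnova(Y)
  # independent oracle: direct sums-of-squares decomposition
  S <- nrow(Y); m <- ncol(Y); g <- mean(Y)
  ssC <- S * sum((colMeans(Y) - g)^2)
  ssS <- m * sum((rowMeans(Y) - g)^2)
  ssE <- sum((Y - g)^2) - ssC - ssS
  expect_equal(res$F, (ssC / (m - 1)) / (ssE / ((m - 1) * (S - 1))),
               tolerance = 1e-12)
  # cross-check against stats::aov
  df <- data.frame(acc = as.vector(Y),
                   cond = factor(rep(colnames(Y), each = S)),
                   subj = factor(rep(seq_len(S), m)))
  tab <- summary(aov(acc ~ cond + Error(subj / cond), data = df))
  Faov <- tab[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(res$F, unname(Faov), tolerance = 1e-10)
  expect_true(res$epsilon > 1 / (m - 1) && res$epsilon <= 1)
})

test_that("Greenhouse-Geisser epsilon is 1 for spherical data", {
  withr::with_seed(5, Z <- matrix(rnorm(60), 20, 3))
  # whiten the columns so the sample covariance is exactly the identity
  Zc <- scale(Z, scale = FALSE)
  Y <- Zc %*% solve(chol(cov(Zc)))
  res <- repeatedMeasuresAnova(Y)
  expect_equal(res$epsilon, 1, tolerance = 1e-6)
})

test_that("identical conditions give F = 0 and pairwise p = 1", {
  Y <- matrix(rep(c(0.4, 0.5, 0.6, 0.7), 3), 4, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  res <- repeatedMeasuresAnova(Y)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  pw <- hyperalignR:::pairwisePairedTests(Y)
  expect_true(all(pw$p == 1))
  expect_true(all(pw$pAdjusted == 1))
})

test_that("the pooled two-sample t-test has df = 2S - 2 and handles ties", {
  x <- seq(0.3, 0.8, length.out = 10)
  tt <- hyperalignR:::twoSampleT(x, x)
  expect_equal(tt$t, 0)
  expect_equal(tt$df, 18)
  expect_equal(tt$p, 1)
  withr::with_seed(2, { a <- rnorm(10); b <- rnorm(10) + 0.5 })
  ours <- hyperalignR:::twoSampleT(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # the exact two-tailed 5% critical value, not a hard-coded constant
  expect_equal(qt(0.975, 18), 2.1009, tolerance = 1e-4)
})

test_that("scenario comparison reports per-subject accuracies and stats", {
  st <- tinyStudy(nSubjects = 4, nVoxels = 20, nLatentDims = 5,
                  session1Timepoints = 50, noiseSd = 3, session1NoiseSd = 1,
                  runEffectSd = 0.5)
  cmp <- runComparison(st)
  Y <- accuracies(cmp)
  expect_equal(dim(Y), c(4, 3))
  expect_identical(colnames(Y), c("WSC", "BSC_anat", "BSC_hyper"))
  # per-subject BSC accuracy is the mean over that subject's run folds
  bsc <- cmp@cvResults$BSC_hyper
  manual <- tapply(foldAccuracies(bsc), foldInfo(bsc)$subject, mean)
  expect_equal(unname(Y[, "BSC_hyper"]), as.numeric(manual[rownames(Y)]))
  expect_true(all(c("F", "epsilon", "p") %in% names(cmp@anova)))
  expect_equal(nrow(cmp@pairwise), 3)
  expect_identical(unique(cmp@pairwise$correction), "bonferroni")
  # deterministic given the study: re-running reproduces bit-identically
  cmp2 <- runComparison(st)
  expect_identical(accuracies(cmp2), Y)
})

test_that("within-session hyperalignment never sees the held-out run", {
  st <- tinyStudy(nSubjects = 3, nVoxels = 12, session1Timepoints = 30)
  ws <- runWithinSessionHyperalignment(st, zscore = FALSE)
  # fold plan covers every subject x run pair exactly once
  fi <- foldInfo(ws)
  expect_equal(nrow(fi), 3 * 4)
  expect_equal(nrow(unique(fi)), 3 * 4)
  expect_setequal(unique(fi$subject), names(session2(st)))
  expect_setequal(unique(fi$run), 1:4)
  # noiseless separable study: perfect decoding
  expect_equal(meanAccuracy(ws), 1)
  expect_equal(sum(confusion(ws)), 12 * 3)
})

test_that("leave-one-subject-out generalization runs at minimal size", {
  st <- tinyStudy(nSubjects = 3, nVoxels = 12, session1Timepoints = 30)
  loo <- runLooGeneralization(st, zscore = FALSE)
  expect_equal(length(loo$perSubject), 3)
  expect_equal(loo$meanAccuracy, 1)       # noiseless exact alignment
  expect_equal(unname(loo$subjectAccuracies),
               unname(vapply(loo$perSubject, meanAccuracy, numeric(1))))
  for (cv in loo$perSubject)
    expect_identical(schemeTag(cv), "BSC_hyper_loo")
  expect_error(runLooGeneralization(tinyStudy(nSubjects = 2)), "three")
})

test_that("order-sensitivity summaries recompute from the raw vector", {
  st <- tinyStudy(nSubjects = 3, nVoxels = 10, session1Timepoints = 26,
                  noiseSd = 2, session1NoiseSd = c(0.5, 1.5, 3))
  os <- runOrderSensitivity(st, nPerms = 6, seed = 4)
  raw <- accuracies(os)
  s <- os@summaryStats
  expect_equal(s$median, median(raw), tolerance = 1e-12)
  expect_equal(s$max, max(raw), tolerance = 1e-12)
  q <- unname(quantile(raw, c(0.25, 0.75)))
  expect_equal(c(s$q1, s$q3), q, tolerance = 1e-12)
  iqr <- q[2] - q[1]
  expect_equal(s$whiskerLow, min(raw[raw >= q[1] - 1.5 * iqr]))
  expect_equal(s$whiskerHigh, max(raw[raw <= q[2] + 1.5 * iqr]))
  expect_equal(nrow(os@tTests), 6)
  expect_equal(unique(os@tTests$df), 2 * 3 - 2)
  # same seed reproduces the permutation set
  os2 <- runOrderSensitivity(st, nPerms = 6, seed = 4)
  expect_identical(accuracies(os2), raw)
})
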