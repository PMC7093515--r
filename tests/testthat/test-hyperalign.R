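test_that("Procrustes solves the identity and seeded recovery problems", {
  X <- matrix(rnorm(60), 12, 5)
  tf <- solveProcrustes(X, X)
  expect_lt(frob(rotation(tf) - diag(5)), 1e-8)
  expect_lt(hyperalignR:::procrustesResidual(X, X, tf), 1e-8)
  Q <- randomOrtho(5, seed = 7)
  tf2 <- solveProcrustes(X %*% Q, X)
  expect_lt(frob(rotation(tf2) - t(Q)), 1e-8)
  expect_error(solveProcrustes(X, X[, 1:3]), "identical shape")
  expect_error(solveProcrustes(X[1, , drop = FALSE], X[1, , drop = FALSE]),
               "two rows")
  expect_error(solveProcrustes(matrix(0, 4, 2), matrix(0, 4, 2)), "zero")
})

test_that("the 2-D solution is the analytic rotation and matches the scan", {
  target <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  R90 <- matrix(c(0, -1, 1, 0), 2)        # +90 degree row-vector rotation
  source <- target %*% R90
  tf <- solveProcrustes(source, target)
  expect_lt(frob(rotation(tf) - t(R90)), 1e-10)
  for (s in 1:10) {
    src <- withr::with_seed(s, matrix(rnorm(12), 6, 2))
    tgt <- withr::with_seed(s + 100, matrix(rnorm(12), 6, 2))
    bf <- bruteForce2d(src, tgt, step = 1e-3)
    tf <- solveProcrustes(src, tgt)
    res <- hyperalignR:::procrustesResidual(src, tgt, tf)
    expect_lte(res, bf$residual + 1e-9)
    expect_gte(res, bf$residual - 1e-3 * (frob(src) + 1))
  }
})

test_that("optional scaling fits a single positive multiplier", {
  X <- matrix(rnorm(80), 16, 5)
  Q <- randomOrtho(5, seed = 3)
  tf <- solveProcrustes(X %*% Q * 2, X, allowScaling = TRUE)
  expect_equal(scalingFactor(tf), 0.5, tolerance = 1e-8)
  expect_lt(hyperalignR:::procrustesResidual(X %*% Q * 2, X, tf), 1e-8)
})

test_that("identical subjects give the shared space and identity transforms", {
  X <- matrix(rnorm(200), 20, 10)
  model <- deriveCommonSpace(list(a = X, b = X, c = X))
  expect_lt(frob(csFinal(model) - X), 1e-6)
  for (tf in transforms(model))
    expect_lt(frob(rotation(tf) - diag(10)), 1e-6)
  single <- deriveCommonSpace(list(only = X))
  expect_lt(frob(csFinal(single) - X), 1e-10)
  expect_lt(frob(rotation(transforms(single)[[1]]) - diag(10)), 1e-10)
  expect_error(deriveCommonSpace(list(X, X[, 1:3])), "share")
})

test_that("noiseless rotated subjects align to correlation > 0.999", {
  st <- tinyStudy(nSubjects = 4, nVoxels = 20, nLatentDims = 6,
                  session1Timepoints = 50)
  model <- deriveCommonSpace(session1(st))
  mapped <- lapply(names(session1(st)), function(id)
    seriesData(mapToCommon(session1(st)[[id]], transforms(model)[[id]])))
  for (i in 1:3) for (j in (i + 1):4)
    expect_gt(cor(as.vector(mapped[[i]]), as.vector(mapped[[j]])), 0.999)
  # the final space is itself an exact orthogonal image of each subject
  for (id in names(session1(st))) {
    tf <- solveProcrustes(seriesData(session1(st)[[id]]), csFinal(model))
    expect_lt(hyperalignR:::procrustesResidual(
      seriesData(session1(st)[[id]]), csFinal(model), tf), 1e-6)
  }
  # noiseless case: cs_final equals the mean of the mapped subjects
  meanMapped <- Reduce(`+`, mapped) / length(mapped)
  expect_lt(frob(csFinal(model) - meanMapped), 1e-6)
})

test_that("mapping is shape-preserving and inverted by the transpose", {
  st <- tinyStudy(nSubjects = 2)
  ts <- session1(st)[[1]]
  n <- ncol(seriesData(ts))
  idT <- new("OrthogonalTransform", rotation = diag(n), scaling = 1,
             sourceSubject = "x")
  expect_equal(seriesData(mapToCommon(ts, idT)), seriesData(ts))
  Q <- randomOrtho(n, seed = 5)
  tf <- new("OrthogonalTransform", rotation = Q, scaling = 1,
            sourceSubject = "x")
  back <- new("OrthogonalTransform", rotation = t(Q), scaling = 1,
              sourceSubject = "x")
  roundTrip <- mapToCommon(mapToCommon(ts, tf), back)
  expect_lt(max(abs(seriesData(roundTrip) - seriesData(ts))), 1e-8)
  mapped <- mapToCommon(ts, tf)
  expect_identical(dim(seriesData(mapped)), dim(seriesData(ts)))
  expect_identical(spaceTag(mapped), "common")
  expect_error(mapToCommon(ts, new("OrthogonalTransform",
                                   rotation = diag(3), scaling = 1,
                                   sourceSubject = "x")), "dimension")
})

test_that("a new subject aligns to an existing model without modifying it", {
  # full-rank data: with rank-deficient inputs the Procrustes solution is
  # only determined up to the null space
  st <- tinyStudy(nSubjects = 4, nVoxels = 14, nLatentDims = 14,
                  session1Conditions = 14, session1Timepoints = 60)
  model <- deriveCommonSpace(session1(st)[1:3])
  csBefore <- csFinal(model)
  asTs <- function(M) new("VoxelTimeSeries", data = M,
                          runIds = rep(1L, nrow(M)), trSeconds = 2,
                          subjectId = "new", spaceTag = "anatomical")
  tfSame <- alignNewSubject(model, asTs(csFinal(model)))
  expect_lt(frob(rotation(tfSame) - diag(14)), 1e-6)
  Q <- randomOrtho(14, seed = 9)
  tfQ <- alignNewSubject(model, asTs(csFinal(model) %*% Q))
  expect_lt(frob(rotation(tfQ) - t(Q)), 1e-8)
  expect_identical(csFinal(model), csBefore)
  expect_error(alignNewSubject(model, asTs(csBefore[, 1:5])), "dimensions")
})

test_that("order permutations are seeded, reproducible and exhaustive", {
  st <- tinyStudy(nSubjects = 3, nVoxels = 8, nLatentDims = 3,
                  session1Timepoints = 20)
  a <- permuteSubjectOrders(session1(st), nPerms = 5, seed = 11)
  b <- permuteSubjectOrders(session1(st), nPerms = 5, seed = 11)
  expect_identical(lapply(a, `[[`, "order"), lapply(b, `[[`, "order"))
  ex <- permuteSubjectOrders(session1(st), exhaustive = TRUE)
  orders <- vapply(ex, function(e) paste(e$order, collapse = ","),
                   character(1))
  expect_equal(length(orders), 6)
  expect_equal(anyDuplicated(orders), 0)
  nat <- permuteSubjectOrders(session1(st), nPerms = 3, seed = 2,
                              firstNatural = TRUE)
  expect_identical(nat[[1]]$order, names(session1(st)))
})

test_that("every produced transform is orthogonal and norm-preserving", {
  st <- tinyStudy(nSubjects = 4, nVoxels = 18, noiseSd = 2,
                  session1NoiseSd = 1.5)
  model <- deriveCommonSpace(prepped <- lapply(session1(st), function(ts)
    zscoreTimeSeries(ts, "whole_series")))
  for (id in names(prepped)) {
    Tm <- rotation(transforms(model)[[id]])
    expect_lt(frob(crossprod(Tm) - diag(ncol(Tm))), 1e-6)
    V <- seriesData(prepped[[id]])
    expect_lt(abs(frob(V %*% Tm) - frob(V)), 1e-6)
  }
})
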