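## Small study factories used across test files. Sizes are deliberately tiny
## so that property loops stay fast; the full-size study conditions are
## exercised in test-acceptance.R.

tinyConfig <- function(...) {
  defaults <- list(nSubjects = 3, nVoxels = 16, nLatentDims = 4,
                   session1Timepoints = 40, session1Conditions = 6,
                   nClasses = 3, nRunsSession2 = 4, blocksPerClassPerRun = 1,
                   blockLen = 4, restLen = 2, noiseSd = 0,
                   session1NoiseSd = 0, runEffectSd = 0,
                   anatMisalignment = 0.8, seed = 42)
  do.call(studyConfig, utils::modifyList(defaults, list(...)))
}

tinyStudy <- function(...) generateStudy(tinyConfig(...))

## Deterministic separable pattern set: classes sit at distinct corners of
## feature space, identical in every run (plus optional jitter).
makePatterns <- function(nRuns = 4, nClasses = 3, nVoxels = 6, jitter = 0,
                         subjectId = "subA", spaceTag = "anatomical",
                         seed = 1) {
  classes <- LETTERS[seq_len(nClasses)]
  means <- diag(nClasses) * 3
  means <- cbind(means, matrix(0, nClasses, nVoxels - nClasses))
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nRuns), function(r)
      means + matrix(rnorm(nClasses * nVoxels, sd = jitter),
                     nClasses, nVoxels)))
  })
  new("LabeledPatternSet", patterns = rows,
      classLabels = rep(classes, nRuns),
      runIds = rep(seq_len(nRuns), each = nClasses),
      subjectId = subjectId, spaceTag = spaceTag)
}

randomOrtho <- function(n, seed = 1) {
  withr::with_seed(seed, {
    qrd <- qr(matrix(rnorm(n * n), n, n))
    Q <- qr.Q(qrd)
    d <- sign(diag(qr.R(qrd))); d[d == 0] <- 1
    sweep(Q, 2, d, `*`)
  })
}

frob <- function(M) sqrt(sum(M^2))

## Closed-form 2x2 Procrustes oracle: the residual of source %*% R - target
## over rotations R(theta) and reflections F(theta) reduces to a trig
## expression in the cross-product matrix M = source' target, so a dense
## angle grid can be scanned exactly.
bruteForce2d <- function(source, target, step = 1e-4) {
  M <- crossprod(source, target)
  theta <- seq(0, 2 * pi, by = step)
  base <- sum(source^2) + sum(target^2)
  trRot <- (M[1, 1] + M[2, 2]) * cos(theta) +
    (M[1, 2] - M[2, 1]) * sin(theta)
  trRef <- (M[1, 1] - M[2, 2]) * cos(theta) +
    (M[1, 2] + M[2, 1]) * sin(theta)
  rotRes <- base - 2 * trRot
  refRes <- base - 2 * trRef
  iRot <- which.min(rotRes); iRef <- which.min(refRes)
  if (rotRes[iRot] <= refRes[iRef]) {
    th <- theta[iRot]
    list(T = matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2),
         residual = sqrt(max(rotRes[iRot], 0)))
  } else {
    th <- theta[iRef]
    list(T = matrix(c(cos(th), sin(th), sin(th), -cos(th)), 2),
         residual = sqrt(max(refRes[iRef], 0)))
  }
}

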