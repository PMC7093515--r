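#' Create a study configuration
#'
#' Defaults mirror a ten-subject motor-imagery decoding study: a rich
#' session-1 time series (many condition patterns in a block design) used to
#' derive the common model space, and a session-2 block design with 3
#' classes (lift, knock, throw) x 8 runs, 3 blocks per class per run, 16 s
#' blocks at TR = 2 s. The 130-voxel default matches a searchlight-selected
#' region of interest; the latent dimensionality of 25 mirrors the 25
#' session-1 conditions.
#'
#' @param nSubjects,nVoxels,nLatentDims,session1Timepoints,session1Conditions
#'   study dimensions; see \linkS4class{StudyConfig}.
#' @param nClasses,nRunsSession2,blocksPerClassPerRun,blockLen,restLen
#'   session-2 block design; see \linkS4class{StudyConfig}.
#' @param trSeconds repetition time in seconds.
#' @param classSep latent class-mean scale (class separability).
#' @param runEffectSd scale of the run-specific, subject-shared modulation
#'   of the latent class patterns (session-time-locked drift of imagery
#'   vividness and attention; 0 disables it). It limits how well a
#'   classifier trained on a subject's other runs transfers to a held-out
#'   run, while leaving same-run transfer across subjects intact.
#' @param noiseSd additive voxel noise SD for the session-2 classification
#'   data, scalar or per subject.
#' @param session1NoiseSd noise SD for the session-1 alignment data
#'   (default 1, i.e. per-timepoint SNR near 1: the alignment session
#'   emulates a long, robust stimulation protocol, while the pure
#'   motor-imagery session-2 data are far noisier per timepoint and rely on
#'   block averaging).
#' @param anatMisalignment fraction of voxels scrambled across subjects in
#'   anatomical space.
#' @param seed integer seed.
#' @return a validated \linkS4class{StudyConfig}.
#' @examples
#' cfg <- studyConfig(nSubjects = 4, nVoxels = 20, nLatentDims = 5,
#'                    session1Timepoints = 40, noiseSd = 0)
#' @export
studyConfig <- function(nSubjects = 10, nVoxels = 130, nLatentDims = 25,
                        session1Timepoints = 640, session1Conditions = 25,
                        nClasses = 3, nRunsSession2 = 8,
                        blocksPerClassPerRun = 3, blockLen = 8, restLen = 4,
                        trSeconds = 2, classSep = 1, runEffectSd = 1,
                        noiseSd = 11, session1NoiseSd = 1,
                        anatMisalignment = 0.8, seed = 1) {
  new("StudyConfig", nSubjects = nSubjects, nVoxels = nVoxels,
      nLatentDims = nLatentDims, session1Timepoints = session1Timepoints,
      session1Conditions = session1Conditions, nClasses = nClasses,
      nRunsSession2 = nRunsSession2,
      blocksPerClassPerRun = blocksPerClassPerRun, blockLen = blockLen,
      restLen = restLen, trSeconds = trSeconds, classSep = classSep,
      runEffectSd = runEffectSd, noiseSd = noiseSd,
      session1NoiseSd = session1NoiseSd,
      anatMisalignment = anatMisalignment, seed = seed)
}

## Haar-uniform orthogonal matrix: QR of a Gaussian matrix with the signs of
## diag(R) folded into Q.
randomOrthogonal <- function(n) {
  if (n == 1) return(matrix(sample(c(-1, 1), 1), 1, 1))
  qrd <- qr(matrix(rnorm(n * n), n, n))
  Q <- qr.Q(qrd)
  d <- sign(diag(qr.R(qrd)))
  d[d == 0] <- 1
  sweep(Q, 2, d, `*`)
}

classNamesFor <- function(nClasses) {
  if (nClasses == 3) c("knock", "lift", "throw")
  else sprintf("class%02d", seq_len(nClasses))
}

## Session-2 block design for one run: a lead-in rest period, then the
## shuffled class blocks, each followed by an inter-block rest.
buildRunDesign <- function(classes, blocksPerClass, blockLen, restLen) {
  blockClasses <- sample(rep(classes, blocksPerClass))
  cls <- rep(NA_character_, restLen)
  blk <- rep(NA_integer_, restLen)
  for (b in seq_along(blockClasses)) {
    cls <- c(cls, rep(blockClasses[b], blockLen), rep(NA_character_, restLen))
    blk <- c(blk, rep(b, blockLen), rep(NA_integer_, restLen))
  }
  data.frame(block = blk, class = cls, stringsAsFactors = FALSE)
}

#' Generate a synthetic two-session multi-subject study
#'
#' All subjects observe one shared latent representational space through a
#' subject-specific orthogonal voxel basis plus i.i.d. Gaussian noise.
#' Session 1 is a rich condition block design (the signal hyperalignment is
#' derived from); session 2 is the labelled classification dataset. The
#' anatomical misalignment fraction controls how much of each subject's
#' orthogonal basis departs from the identity: a fraction
#' \code{anatMisalignment} of voxel coordinates is mixed by a random
#' orthogonal rotation (and recorded as a scrambled subset), the remainder
#' keeps its voxel identity, so anatomical-space correspondence across
#' subjects is partial while an exact orthogonal alignment always exists.
#'
#' With \code{noiseSd = 0} any two subjects' matrices are exact orthogonal
#' images of one another. Identical seeds give bit-identical output.
#'
#' @param config a \linkS4class{StudyConfig}.
#' @return a \linkS4class{SyntheticStudy}.
#' @examples
#' study <- generateStudy(studyConfig(nSubjects = 3, nVoxels = 16,
#'   nLatentDims = 4, session1Timepoints = 30, blocksPerClassPerRun = 1,
#'   blockLen = 2, restLen = 1, noiseSd = 0))
#' @export
generateStudy <- function(config) {
  validObject(config)
  S <- config@nSubjects; n <- config@nVoxels; d <- config@nLatentDims
  k1 <- config@session1Timepoints
  noise <- rep(config@noiseSd, length.out = S)
  noise1 <- rep(config@session1NoiseSd, length.out = S)
  classes <- classNamesFor(config@nClasses)

  withr::with_seed(as.integer(config@seed), {
    ## shared latent geometry -------------------------------------------
    condPatterns <- matrix(rnorm(config@session1Conditions * d),
                           config@session1Conditions, d)
    nBlocks1 <- ceiling(k1 / config@blockLen)
    condSeq <- unlist(lapply(seq_len(ceiling(
      nBlocks1 / config@session1Conditions)),
      function(i) sample(config@session1Conditions)))[seq_len(nBlocks1)]
    latent1 <- condPatterns[rep(condSeq, each = config@blockLen)[seq_len(k1)],
                            , drop = FALSE]
    ## slow sinusoidal component so the latent series is full rank and has
    ## smooth within-block structure
    t1 <- seq_len(k1)
    nWaves <- min(d, 6)
    waves <- sapply(seq_len(nWaves), function(j)
      sin(2 * pi * t1 / (k1 / j) + runif(1, 0, 2 * pi)))
    latent1 <- latent1 + waves %*% matrix(rnorm(nWaves * d, sd = 0.5),
                                          nWaves, d)

    embedding <- t(qr.Q(qr(matrix(rnorm(n * d), n, d))))  # d x n rows o.n.
    common1 <- latent1 %*% embedding
    common1 <- scale(common1, center = TRUE, scale = FALSE)
    sds <- apply(common1, 2, sd)
    sds[sds < 1e-12] <- 1
    common1 <- sweep(common1, 2, sds, `/`)

    classMeans <- matrix(rnorm(config@nClasses * d, sd = config@classSep),
                         config@nClasses, d,
                         dimnames = list(classes, NULL))
    ## run-specific class-pattern modulation, shared across subjects
    runClassMeans <- lapply(seq_len(config@nRunsSession2), function(r)
      classMeans + matrix(rnorm(config@nClasses * d,
                                sd = config@runEffectSd),
                          config@nClasses, d))

    ## session-2 design (shared across subjects) ------------------------
    labs <- do.call(rbind, lapply(seq_len(config@nRunsSession2), function(r) {
      des <- buildRunDesign(classes, config@blocksPerClassPerRun,
                            config@blockLen, config@restLen)
      cbind(run = r, des)
    }))
    labs <- data.frame(timepoint = seq_len(nrow(labs)), run = labs$run,
                       block = labs$block, class = labs$class,
                       stringsAsFactors = FALSE)
    common2 <- matrix(0, nrow(labs), n)
    labelled <- which(!is.na(labs$class))
    common2[labelled, ] <- (do.call(rbind, lapply(labelled, function(i)
      runClassMeans[[labs$run[i]]][labs$class[i], ]))) %*% embedding

    ## per-subject bases and observations -------------------------------
    nScrambled <- round(config@anatMisalignment * n)
    bases <- vector("list", S); perms <- vector("list", S)
    scrambled <- vector("list", S)
    sess1 <- vector("list", S); sess2 <- vector("list", S)
    ids <- sprintf("sub%02d", seq_len(S))
    for (s in seq_len(S)) {
      idx <- if (nScrambled > 0) sort(sample(n, nScrambled)) else integer(0)
      B <- diag(n)
      if (nScrambled >= 1) B[idx, idx] <- randomOrthogonal(nScrambled)
      p <- seq_len(n)
      if (nScrambled >= 2) p[idx] <- idx[sample(nScrambled)]
      bases[[s]] <- B; perms[[s]] <- p; scrambled[[s]] <- idx

      v1 <- common1 %*% B +
        matrix(rnorm(k1 * n, sd = noise1[s]), k1, n)
      v2 <- common2 %*% B +
        matrix(rnorm(nrow(common2) * n, sd = noise[s]), nrow(common2), n)
      sess1[[s]] <- new("VoxelTimeSeries", data = v1,
                        runIds = rep(1L, k1), trSeconds = config@trSeconds,
                        subjectId = ids[s], spaceTag = "anatomical")
      sess2[[s]] <- new("VoxelTimeSeries", data = v2,
                        runIds = as.integer(labs$run),
                        trSeconds = config@trSeconds, subjectId = ids[s],
                        spaceTag = "anatomical")
    }
    names(sess1) <- names(sess2) <- ids
    names(bases) <- names(perms) <- names(scrambled) <- ids

    new("SyntheticStudy", config = config, session1 = sess1,
        session2 = sess2, labels = labs,
        groundTruth = list(latentSession1 = latent1,
                           latentClassMeans = classMeans,
                           runClassMeans = runClassMeans,
                           embedding = embedding,
                           session1Common = common1,
                           session2Common = common2,
                           subjectBases = bases,
                           anatPermutations = perms,
                           scrambledVoxels = scrambled))
  })
}

#' Permute voxel identities of a time series
#'
#' Reorders the columns of a voxel time series according to a bijective
#' voxel reindexing (column j of the output is column \code{permutation[j]}
#' of the input). Used to model residual anatomical misalignment: values are
#' unchanged as a multiset, only voxel identity is scrambled.
#'
#' @param ts a \linkS4class{VoxelTimeSeries}.
#' @param permutation integer vector, a permutation of \code{1:nVoxels}.
#' @return the reordered \linkS4class{VoxelTimeSeries}.
#' @export
applyAnatMisalignment <- function(ts, permutation) {
  stopifnot(is(ts, "VoxelTimeSeries"))
  n <- ncol(ts@data)
  if (length(permutation) != n || !setequal(permutation, seq_len(n)))
    stop("'permutation' must be a bijection on the voxel indices 1..", n)
  ts@data <- ts@data[, permutation, drop = FALSE]
  ts
}
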