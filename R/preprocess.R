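#' Z-score a voxel time series
#'
#' Normalizes every voxel column to mean 0 and standard deviation 1, either
#' within each run (default; runs are independently acquired) or across the
#' whole series. A zero-variance voxel is an error rather than silently
#' dropped, because voxel correspondence across subjects must be preserved
#' for Procrustes alignment.
#'
#' @param ts a \linkS4class{VoxelTimeSeries}.
#' @param scope \code{"per_run"} or \code{"whole_series"}.
#' @return the normalized \linkS4class{VoxelTimeSeries}.
#' @export
zscoreTimeSeries <- function(ts, scope = c("per_run", "whole_series")) {
  scope <- match.arg(scope)
  stopifnot(is(ts, "VoxelTimeSeries"))
  X <- ts@data
  groups <- if (scope == "per_run") ts@runIds else rep(1L, nrow(X))
  for (g in unique(groups)) {
    rows <- which(groups == g)
    block <- X[rows, , drop = FALSE]
    mu <- colMeans(block)
    sdv <- apply(block, 2, sd)
    bad <- which(sdv < 1e-12)
    if (length(bad))
      stop(sprintf("zero-variance voxel %d in run %s; cannot z-score",
                   bad[1], if (scope == "per_run") g else "(whole series)"))
    X[rows, ] <- sweep(sweep(block, 2, mu, `-`), 2, sdv, `/`)
  }
  ts@data <- X
  ts
}

#' Shift labels to account for the hemodynamic delay
#'
#' Re-associates each per-timepoint annotation with the data acquired
#' \code{nTrs} repetition times later (with TR = 2 s the default 2-TR shift
#' is the conventional 4 s hemodynamic delay). The shift is applied within
#' runs and never crosses run boundaries: annotations that would fall past
#' the end of their run are dropped, and the first \code{nTrs} timepoints of
#' every run are left unannotated. Labels are re-indexed; the data are never
#' resampled.
#'
#' @param labels data.frame with columns \code{timepoint}, \code{run},
#'   \code{block}, \code{class} covering every timepoint of the series
#'   (class \code{NA} at rest).
#' @param nTrs nonnegative integer shift in TRs (default 2).
#' @return the shifted labels data.frame, same shape and timepoints.
#' @export
shiftForHemodynamics <- function(labels, nTrs = 2) {
  stopifnot(is.data.frame(labels),
            all(c("timepoint", "run", "block", "class") %in% names(labels)))
  if (length(nTrs) != 1 || nTrs < 0 || nTrs != round(nTrs))
    stop("'nTrs' must be a single nonnegative integer")
  out <- labels
  out$class <- NA_character_
  out$block <- NA_integer_
  for (r in unique(labels$run)) {
    rows <- which(labels$run == r)
    if (nTrs >= length(rows))
      stop(sprintf("shift of %d TRs is not shorter than run %s (%d TRs)",
                   nTrs, r, length(rows)))
    if (nTrs > 0) {
      src <- rows[seq_len(length(rows) - nTrs)]
      dst <- rows[seq_len(length(rows) - nTrs) + nTrs]
    } else {
      src <- dst <- rows
    }
    out$class[dst] <- labels$class[src]
    out$block[dst] <- labels$block[src]
  }
  out
}

#' Average stimulus blocks into labelled response patterns
#'
#' Averages, within each run, all timepoints annotated with the same class
#' (across that class's blocks) into a single response pattern, so that a
#' run with three stimulus classes yields exactly three pattern vectors.
#' Labels must already be aligned to the data rows (after any hemodynamic
#' shift).
#'
#' @param ts a \linkS4class{VoxelTimeSeries}.
#' @param labels per-timepoint annotation data.frame as in
#'   \code{\link{shiftForHemodynamics}}.
#' @return a \linkS4class{LabeledPatternSet} ordered by run, then class.
#' @export
averageBlocks <- function(ts, labels) {
  stopifnot(is(ts, "VoxelTimeSeries"), is.data.frame(labels))
  if (nrow(labels) != nrow(ts@data))
    stop("labels must annotate every timepoint of the series")
  classes <- sort(unique(labels$class[!is.na(labels$class)]))
  if (length(classes) == 0) stop("no labelled timepoints")
  runs <- unique(ts@runIds)
  missing <- list()
  pats <- list(); cls <- character(0); rids <- integer(0)
  for (r in runs) {
    for (cl in classes) {
      rows <- which(ts@runIds == r & !is.na(labels$class) &
                      labels$class == cl)
      if (length(rows) == 0) {
        missing[[length(missing) + 1]] <- sprintf("(run %s, class %s)", r, cl)
        next
      }
      pats[[length(pats) + 1]] <- colMeans(ts@data[rows, , drop = FALSE])
      cls <- c(cls, cl); rids <- c(rids, as.integer(r))
    }
  }
  if (length(missing))
    stop("class absent from run: ", paste(unlist(missing), collapse = ", "))
  new("LabeledPatternSet", patterns = do.call(rbind, pats),
      classLabels = cls, runIds = rids, subjectId = ts@subjectId,
      spaceTag = ts@spaceTag)
}
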