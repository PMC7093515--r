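## Plain-text IO. Matrices are written as TSV with full double precision
## ("%.17g") so a write-then-read round trip is bit-identical.

formatFull <- function(x) {
  out <- sprintf("%.17g", x)
  dim(out) <- dim(x)
  out
}

#' Write a voxel time series as TSV
#'
#' First column \code{run}, then one column per voxel (\code{v1 ... vn}),
#' values printed with 17 significant digits so the round trip through
#' \code{\link{readTimeSeriesTSV}} is bit-identical.
#'
#' @param ts a \linkS4class{VoxelTimeSeries}.
#' @param path output file path.
#' @export
writeTimeSeriesTSV <- function(ts, path) {
  stopifnot(is(ts, "VoxelTimeSeries"))
  tab <- cbind(run = ts@runIds, formatFull(ts@data))
  colnames(tab) <- c("run", sprintf("v%d", seq_len(ncol(ts@data))))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a voxel time series written by \code{\link{writeTimeSeriesTSV}}
#'
#' @param path TSV file path.
#' @param subjectId,spaceTag,trSeconds metadata for the restored object.
#' @return a \linkS4class{VoxelTimeSeries}.
#' @export
readTimeSeriesTSV <- function(path, subjectId = "unknown",
                              spaceTag = "anatomical", trSeconds = 2) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  new("VoxelTimeSeries",
      data = unname(as.matrix(tab[, -1, drop = FALSE])),
      runIds = as.integer(tab$run), trSeconds = trSeconds,
      subjectId = subjectId, spaceTag = spaceTag)
}

#' Write a synthetic study to a directory
#'
#' Writes one TSV per subject per session, the session-2 labels table, the
#' ground-truth matrices (TSV) and a JSON provenance record (configuration,
#' seed, package and R versions) sufficient to regenerate the study
#' bit-identically.
#'
#' @param study a \linkS4class{SyntheticStudy}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(session1(study))) {
    writeTimeSeriesTSV(session1(study)[[id]],
                       file.path(dir, paste0(id, "_session1.tsv")))
    writeTimeSeriesTSV(session2(study)[[id]],
                       file.path(dir, paste0(id, "_session2.tsv")))
  }
  write.table(studyLabels(study), file.path(dir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  gtDir <- file.path(dir, "ground_truth")
  dir.create(gtDir, showWarnings = FALSE)
  gt <- groundTruth(study)
  for (nm in c("latentSession1", "latentClassMeans", "embedding")) {
    m <- formatFull(gt[[nm]])
    write.table(m, file.path(gtDir, paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  writeProvenance(file.path(dir, "provenance.json"),
                  config = configAsList(studyConfigOf(study)))
  invisible(dir)
}

configAsList <- function(cfg) {
  out <- lapply(slotNames(cfg), function(s) slot(cfg, s))
  names(out) <- slotNames(cfg)
  out
}

writeProvenance <- function(path, ...) {
  rec <- list(..., package = "hyperalignR",
              packageVersion = as.character(packageVersion("hyperalignR")),
              rVersion = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a cross-validation result as TSV tables
#'
#' Writes the per-fold accuracies (with fold descriptors) and the confusion
#' matrix next to each other.
#'
#' @param cv a \linkS4class{CVResult}.
#' @param prefix output path prefix; \code{<prefix>_folds.tsv} and
#'   \code{<prefix>_confusion.tsv} are written.
#' @export
writeCVResultTSV <- function(cv, prefix) {
  folds <- cbind(foldInfo(cv), accuracy = foldAccuracies(cv))
  write.table(folds, paste0(prefix, "_folds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(confusion(cv), paste0(prefix, "_confusion.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  invisible(prefix)
}

#' Load a masked 4D NIfTI time series
#'
#' Extracts the voxel x time matrix inside a binary mask. Voxel order is
#' the ascending linear index over the image grid with the first (x) axis
#' fastest, 0-based -- R's native array order -- and is recorded in the
#' returned object's metadata attribute \code{"voxelOrder"}.
#'
#' @param imagePath path to a 4D NIfTI image.
#' @param maskPath path to a 3D NIfTI mask on the same grid (nonzero =
#'   inside).
#' @param subjectId,spaceTag metadata for the returned series.
#' @param runIds optional per-volume run labels (default: a single run).
#' @return a \linkS4class{VoxelTimeSeries} (timepoints x mask voxels).
#' @export
loadMaskedTimeseries <- function(imagePath, maskPath,
                                 subjectId = "unknown",
                                 spaceTag = "anatomical", runIds = NULL) {
  img <- RNifti::readNifti(imagePath)
  mask <- RNifti::readNifti(maskPath)
  di <- dim(img); dm <- dim(mask)
  if (length(di) != 4)
    stop("'imagePath' must be a 4D image, got ", length(di), " dimensions")
  if (!identical(di[1:3], dm[1:3]))
    stop("image grid ", paste(di[1:3], collapse = "x"),
         " does not match mask grid ", paste(dm, collapse = "x"))
  keep <- which(as.vector(mask) != 0)
  if (length(keep) == 0) stop("mask is empty")
  vol <- matrix(as.vector(img), prod(di[1:3]), di[4])
  data <- t(vol[keep, , drop = FALSE])
  tr <- tryCatch(RNifti::pixdim(img)[4], error = function(e) NA_real_)
  if (!length(tr) || !is.finite(tr) || tr <= 0) tr <- 2
  if (is.null(runIds)) runIds <- rep(1L, di[4])
  ts <- new("VoxelTimeSeries", data = data, runIds = as.integer(runIds),
            trSeconds = tr, subjectId = subjectId, spaceTag = spaceTag)
  attr(ts@data, "voxelOrder") <- "linear index over grid, x fastest, 0-based"
  ts
}

#' Write a searchlight map into a mask NIfTI
#'
#' Places each mask voxel's accuracy at its grid position (same voxel order
#' convention as \code{\link{loadMaskedTimeseries}}) and writes a 3D NIfTI.
#'
#' @param map a \linkS4class{SearchlightMap}.
#' @param maskPath the mask NIfTI that defined the voxel order.
#' @param outPath output NIfTI path.
#' @export
writeSearchlightNifti <- function(map, maskPath, outPath) {
  mask <- RNifti::readNifti(maskPath)
  keep <- which(as.vector(mask) != 0)
  if (length(keep) != length(map@accuracies))
    stop("mask voxel count does not match the searchlight map")
  vol <- array(0, dim(mask))
  vol[keep] <- map@accuracies
  RNifti::writeNifti(RNifti::asNifti(vol, reference = mask), outPath)
  invisible(outPath)
}

studyConfigKeys <- function() {
  c("nSubjects", "nVoxels", "nLatentDims", "session1Timepoints",
    "session1Conditions", "nClasses", "nRunsSession2",
    "blocksPerClassPerRun", "blockLen", "restLen", "trSeconds", "classSep",
    "runEffectSd", "noiseSd", "session1NoiseSd", "anatMisalignment", "seed")
}

#' Load a study/run configuration from YAML
#'
#' Flat key-value schema: any \linkS4class{StudyConfig} field, plus an
#' optional \code{experiment} section with run options (\code{nPerms},
#' \code{zscore}, \code{shiftTrs}, \code{cRaw}, \code{allowScaling}).
#' Unknown keys are an error, not a warning, so a typo cannot silently
#' corrupt a simulation. Omitted keys take the documented
#' \code{\link{studyConfig}} defaults. The returned object carries the
#' file's MD5 fingerprint.
#'
#' @param path YAML file path.
#' @return list with \code{config} (\linkS4class{StudyConfig}),
#'   \code{experiment} (named list of run options) and \code{fingerprint}.
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  expOpts <- raw$experiment
  raw$experiment <- NULL
  unknown <- setdiff(names(raw), studyConfigKeys())
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  expKeys <- c("nPerms", "zscore", "shiftTrs", "cRaw", "allowScaling",
               "radiusVoxels")
  if (!is.null(expOpts)) {
    badExp <- setdiff(names(expOpts), expKeys)
    if (length(badExp))
      stop("unknown experiment key(s): ", paste(badExp, collapse = ", "))
  }
  expDefaults <- list(nPerms = 2000, zscore = TRUE, shiftTrs = 2,
                      cRaw = -1, allowScaling = FALSE, radiusVoxels = 3)
  expOpts <- utils::modifyList(expDefaults,
                               if (is.null(expOpts)) list() else expOpts)
  cfg <- tryCatch(do.call(studyConfig, raw), error = function(e)
    stop("invalid configuration: ", conditionMessage(e), call. = FALSE))
  list(config = cfg, experiment = expOpts,
       fingerprint = unname(tools::md5sum(path)))
}
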