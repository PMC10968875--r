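#' Read a time-lapse sequence
#'
#' Reads either a multi-frame grayscale TIFF stack or a directory of
#' lexicographically ordered single-frame TIFF/PNG images. Color inputs are
#' converted to grayscale by the unweighted channel mean (the instrument
#' itself produces grayscale; this only matters for test fixtures).
#'
#' @param path a TIFF file or a directory of frames
#' @param meta an [AcquisitionMeta-class] attached to the sequence
#' @return a [VideoSequence-class]
#' @examples
#' sc <- sceneConfig(nCells = 0, nBeads = 5, nFrames = 2,
#'                   fieldSize = c(64, 64), noiseSd = 0)
#' sim <- simulateScene(sc)
#' f <- tempfile(fileext = ".tif")
#' writeSequence(sim$sequence, f)
#' seq2 <- readSequence(f)
#' length(seq2)
#' @export
readSequence <- function(path, meta = acquisitionMeta()) {
  if (!file.exists(path))
    .bp_stop("beadphage_missing_path", sprintf("path does not exist: %s", path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE)
    files <- file.path(path, sort(files, method = "radix"))
    if (length(files) == 0)
      .bp_stop("beadphage_zero_frames",
               sprintf("no TIFF/PNG frames found in %s", path))
    frames <- lapply(files, .read_frame)
  } else {
    raw <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(raw)) raw <- list(raw)
    if (length(raw) == 0)
      .bp_stop("beadphage_zero_frames", sprintf("no frames in %s", path))
    frames <- lapply(raw, .to_gray)
  }
  d <- dim(frames[[1]])
  bad <- which(!vapply(frames, function(f) identical(dim(f), d), logical(1)))
  if (length(bad))
    .bp_stop("beadphage_dim_mismatch",
             sprintf("frame %d dimensions differ from frame 1", bad[1]))
  videoSequence(frames, meta)
}

.read_frame <- function(file) {
  a <- if (grepl("\\.png$", file, ignore.case = TRUE)) png::readPNG(file)
       else tiff::readTIFF(file)
  .to_gray(a)
}

.to_gray <- function(a) {
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)  # channel mean
  storage.mode(a) <- "double"
  a
}

#' Write a sequence as a 16-bit multi-frame TIFF
#'
#' Intensities must lie in [0, 1]; they are stored on the 16-bit grid, so a
#' sequence already quantized to that grid (as [simulateScene()] output is)
#' round-trips through [readSequence()] bit-exactly.
#'
#' @param x a [VideoSequence-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeSequence <- function(x, path) {
  stopifnot(is(x, "VideoSequence"))
  rng <- range(vapply(x@frames, range, numeric(2)))
  if (rng[2] > 1)
    .bp_stop("beadphage_intensity_range",
             "writeSequence expects intensities in [0, 1]")
  ok <- tryCatch(tiff::writeTIFF(x@frames, path, bits.per.sample = 16L),
                 error = function(e) .bp_stop("beadphage_unwritable",
                                              conditionMessage(e)))
  invisible(path)
}

# Fixed column orders for the tabular outputs (documented contract).
.bp_columns <- list(
  detection = c("frame", "index", "x", "y", "area", "brightness", "contrast",
                "label", "bead_count"),
  track     = c("track_id", "frame", "time_min", "x", "y"),
  series    = c("frame", "time_min", "free", "ingested", "smoothed",
                "per_cell", "per_bead", "cells"))

#' Write a homogeneous record table as CSV
#'
#' Writes RFC-4180 CSV with a fixed, documented column order per record
#' type and numeric fields at full (17 significant digit) precision, so a
#' write/read cycle through [readRecords()] reproduces the records exactly.
#' An empty record list yields a header-only file.
#'
#' @param records data.frame of one record type
#' @param path output file
#' @param type one of "detection", "track", "series", or "as_is" to keep the
#'   columns as given
#' @return `path`, invisibly
#' @export
writeRecords <- function(records, path,
                         type = c("as_is", "detection", "track", "series")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(records))
  if (type != "as_is") {
    cols <- .bp_columns[[type]]
    missing <- setdiff(cols, names(records))
    if (length(missing))
      .bp_stop("beadphage_bad_records",
               sprintf("records lack columns: %s", paste(missing, collapse = ", ")))
    records <- records[, cols, drop = FALSE]
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = TRUE),
           error = function(e) .bp_stop("beadphage_unwritable",
                                        conditionMessage(e)))
  invisible(path)
}

#' Read a record table written by [writeRecords()]
#'
#' @param path CSV file
#' @param numeric_cols columns to parse as double; defaults to everything
#'   that parses cleanly
#' @return data.frame
#' @export
readRecords <- function(path, numeric_cols = NULL) {
  if (!file.exists(path))
    .bp_stop("beadphage_missing_path", sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- if (is.null(numeric_cols)) names(df) else numeric_cols
  for (j in intersect(cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(v) || all(is.na(df[[j]]) == is.na(v))) df[[j]] <- v
  }
  df
}

#' Write acquisition metadata as a JSON sidecar
#' @param meta an [AcquisitionMeta-class]
#' @param path output .json file
#' @return `path`, invisibly
#' @export
writeMetaJSON <- function(meta, path) {
  jsonlite::write_json(
    list(frame_interval_min = meta@frameInterval,
         pixel_scale_um_per_px = meta@pixelScale,
         duration_min = meta@duration,
         objective = meta@objectiveLabel),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an acquisition metadata JSON sidecar
#' @param path .json file written by [writeMetaJSON()]
#' @return an [AcquisitionMeta-class]
#' @export
readMetaJSON <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  acquisitionMeta(frameInterval = m$frame_interval_min,
                  pixelScale = m$pixel_scale_um_per_px,
                  duration = m$duration_min,
                  objectiveLabel = m$objective %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
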