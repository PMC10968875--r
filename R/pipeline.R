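#' Run the full phagocytosis/migration analysis on a sequence
#'
#' The complete pipeline on one recording:
#' \enumerate{
#'   \item detect bead conglomerates in every frame;
#'   \item link all detections into tracks by optimal assignment;
#'   \item select the motile tracks as cell proxies and build per-frame
#'     cell masks from them;
#'   \item classify every detection free vs ingested (mask coincidence OR
#'     surrounding-contrast criterion);
#'   \item fit the size-brightness diagram and count beads per detection;
#'   \item build the ingestion series (free counts, cumulative ingested,
#'     smoothing, per-cell and per-bead normalization) and the per-track
#'     motion metrics.
#' }
#' The per-frame cell count defaults to the number of motile tracks whose
#' span covers the frame; pass `cellCounts` to substitute manual counts.
#'
#' @param sequence a [VideoSequence-class]
#' @param detParams a [DetectionParams-class]; default derives area bounds
#'   from the sequence's pixel scale
#' @param trkParams a [TrackingParams-class]
#' @param motionWindow robust-regression smoothing window (frames)
#' @param seriesWindow ingestion-curve smoothing window (frames)
#' @param cellCounts optional per-frame cell counts
#' @param a1 optional forced single-bead area for the diagram
#' @return list with `detections`, `tracks`, `cellTracks`, `diagram`,
#'   `series` ([IngestionSeries-class]), `motion` (per-track metrics for
#'   the motile tracks), `capacity`
#' @export
analyzeSequence <- function(sequence, detParams = NULL,
                            trkParams = trackingParams(),
                            motionWindow = 20, seriesWindow = 5,
                            cellCounts = NULL, a1 = NULL) {
  stopifnot(is(sequence, "VideoSequence"))
  meta <- sequence@meta
  if (is.null(detParams)) detParams <- detectionParams(meta@pixelScale)
  nF <- length(sequence)

  dets <- do.call(rbind, lapply(seq_len(nF), function(i) {
    detectConglomerates(sequence[[i]], detParams, frameIndex = i - 1L)
  }))
  if (is.null(dets) || nrow(dets) == 0)
    .bp_stop("beadphage_no_detections", "no conglomerates detected")
  rownames(dets) <- NULL

  tracks <- linkTracks(dets, trkParams, frameInterval = meta@frameInterval)
  ct <- cellTracks(tracks, detParams@minCellDisplacement,
                   detParams@minCellStep)

  d <- dim(sequence)
  labelled <- lapply(0:(nF - 1), function(f) {
    at <- dets[dets$frame == f, , drop = FALSE]
    if (nrow(at) == 0) return(at)
    mask <- buildCellMask(ct, f, d, detParams@maskDilationRadius)
    classifyDetections(at, mask, detParams)
  })
  dets <- do.call(rbind, labelled)
  rownames(dets) <- NULL

  diagram <- fitSizeBrightness(dets, a1 = a1)
  dets$bead_count <- countBeads(dets$area, diagram)

  if (is.null(cellCounts)) {
    cellCounts <- vapply(0:(nF - 1), function(f) {
      if (nrow(ct) == 0) return(0L)
      spans <- tapply(ct$frame, ct$track_id, range)
      sum(vapply(spans, function(r) r[1] <= f && f <= r[2], logical(1)))
    }, integer(1))
  }

  series <- ingestionSeries(dets, cellCounts, meta = meta,
                            window = seriesWindow, nFrames = nF)
  motion <- motionTable(ct, meta = meta, window = motionWindow)
  capacity <- capacityTable(ct, dets)

  list(detections = dets, tracks = tracks, cellTracks = ct,
       diagram = diagram, series = series, motion = motion,
       capacity = capacity)
}

#' Write the outputs of [analyzeSequence()] as CSV tables
#'
#' Emits `detections.csv`, `tracks.csv`, `series.csv`, `motion.csv` and
#' `capacity.csv` into a directory.
#'
#' @param result list from [analyzeSequence()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeAnalysis <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeRecords(result$detections, file.path(dir, "detections.csv"),
               type = "detection")
  writeRecords(result$tracks[, c("track_id", "frame", "time_min", "x", "y")],
               file.path(dir, "tracks.csv"), type = "track")
  writeRecords(as.data.frame(result$series), file.path(dir, "series.csv"),
               type = "series")
  writeRecords(result$motion, file.path(dir, "motion.csv"))
  writeRecords(result$capacity, file.path(dir, "capacity.csv"))
  invisible(dir)
}
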