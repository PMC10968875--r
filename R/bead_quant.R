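#' Fit the size-brightness diagram
#'
#' Builds a 2-D histogram of (area, mean brightness) over all detections,
#' takes the dominant density peak as the single-bead mode `a1`, and then
#' confirms hotspots near `k * a1` (k = 2, 3, ...) against the histogram:
#' a hotspot is accepted when enough points fall within +/-25% of `a1`
#' around `k * a1`. Detections beyond the last hotspot are handled by the
#' recorded outlier rule, area division by `a1` (see [countBeads()]).
#'
#' @param points data.frame with columns `area` and `brightness` (a
#'   detection table works as-is)
#' @param nAreaBins,nBrightnessBins histogram resolution
#' @param minHotspotFraction fraction of points (with a floor of 3) needed
#'   to confirm a multi-bead hotspot
#' @param maxHotspots stop confirming beyond this many beads
#' @param a1 optionally force the single-bead modal area instead of
#'   estimating it (the escape hatch when no dominant peak exists)
#' @return a [SizeBrightnessDiagram-class]
#' @export
fitSizeBrightness <- function(points, nAreaBins = 64, nBrightnessBins = 16,
                              minHotspotFraction = 0.02, maxHotspots = 10,
                              a1 = NULL) {
  stopifnot(all(c("area", "brightness") %in% names(points)))
  pts <- points[, c("area", "brightness")]
  if (nrow(pts) < 10)
    .bp_stop("beadphage_too_few_points",
             sprintf("need >= 10 detections to fit the diagram, got %d",
                     nrow(pts)))
  if (is.null(a1)) {
    ab <- .binIndex(pts$area, nAreaBins)
    bb <- .binIndex(pts$brightness, nBrightnessBins)
    counts <- table(factor(ab, levels = seq_len(nAreaBins)),
                    factor(bb, levels = seq_len(nBrightnessBins)))
    peak <- which(counts == max(counts), arr.ind = TRUE)[1, ]
    mode_area <- stats::median(pts$area[ab == peak[1]])
    sel <- abs(pts$area - mode_area) <= 0.25 * mode_area
    # dominance is judged on the area marginal around the modal cell: the
    # single-bead cluster must hold a material share of all detections
    if (sum(sel) < max(5, 0.1 * nrow(pts)))
      .bp_stop("beadphage_no_dominant_peak",
               paste("no dominant density peak in the size-brightness",
                     "diagram; supply the single-bead area a1 explicitly"))
    a1 <- mean(pts$area[sel])
  }
  hs <- a1
  nmin <- max(3, ceiling(minHotspotFraction * nrow(pts)))
  for (k in 2:maxHotspots) {
    sel <- abs(pts$area - k * a1) <= 0.25 * a1
    if (sum(sel) < nmin) break
    cand <- mean(pts$area[sel])
    if (cand <= hs[length(hs)]) break
    hs <- c(hs, cand)
  }
  new("SizeBrightnessDiagram", points = pts, hotspots = hs,
      outlierRule = "bead count = max(1, round(area / a1))")
}

.binIndex <- function(v, nbins) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  pmin(nbins, 1L + floor((v - r[1]) / (r[2] - r[1]) * nbins))
}

#' Count beads in a conglomerate from its area
#'
#' The nearest hotspot index when the area lies within +/-25% of `a1` of
#' that hotspot; beyond that, large outliers with bead-like brightness are
#' estimated by area division, `max(1, round(area / a1))`.
#'
#' @param area numeric vector of component areas (px^2)
#' @param diagram a fitted [SizeBrightnessDiagram-class]
#' @return integer bead counts, all >= 1
#' @export
countBeads <- function(area, diagram) {
  stopifnot(is(diagram, "SizeBrightnessDiagram"))
  hs <- diagram@hotspots
  a1 <- hs[1]
  vapply(area, function(a) {
    k <- which.min(abs(hs - a))
    if (abs(hs[k] - a) <= 0.25 * a1) k
    else max(1L, as.integer(round(a / a1)))
  }, integer(1))
}

#' Centered moving-window smoother
#'
#' Centered moving average (or median) of length `window`; at the series
#' ends the window shrinks to what is available. Output never leaves the
#' [min, max] range of the input.
#'
#' @param x numeric vector
#' @param window window length in frames (default 5)
#' @param method "mean" or "median"
#' @return numeric vector, same length
#' @export
movingSmooth <- function(x, window = 5, method = c("mean", "median")) {
  method <- match.arg(method)
  fun <- if (method == "mean") mean else stats::median
  n <- length(x)
  half <- (window - 1) / 2
  vapply(seq_len(n), function(t) {
    lo <- max(1, ceiling(t - half)); hi <- min(n, floor(t + half))
    fun(x[lo:hi])
  }, numeric(1))
}

#' Build the ingestion time series
#'
#' Sums bead counts over the free-labelled detections of each frame, then
#' subtracts from the free count of the first frame to obtain the
#' cumulative ingested count (the recording is assumed to start before any
#' ingestion has occurred). The cumulative curve is smoothed with a
#' centered moving window and normalized per cell and per initially
#' available bead. Detection noise can push the instantaneous free count
#' above the first frame's; the resulting negative ingested values are
#' clamped to zero and the number of clamped frames reported via a message.
#'
#' @param detections labelled detection table with `bead_count` filled
#' @param cellCounts integer vector, cells in the field per frame (recycled
#'   if length 1); frames with zero cells get `NA` per-cell values
#' @param meta an [AcquisitionMeta-class] for timestamps
#' @param window smoothing window in frames
#' @param method smoothing method, "mean" or "median"
#' @param nFrames number of frames (defaults to max frame index + 1)
#' @return an [IngestionSeries-class]
#' @export
ingestionSeries <- function(detections, cellCounts, meta = acquisitionMeta(),
                            window = 5, method = "mean", nFrames = NULL) {
  stopifnot(all(c("frame", "label", "bead_count") %in% names(detections)))
  if (is.null(nFrames)) nFrames <- max(detections$frame) + 1L
  frames <- 0:(nFrames - 1L)
  free <- integer(nFrames)
  fr <- detections[detections$label == "free", , drop = FALSE]
  if (nrow(fr)) {
    agg <- tapply(fr$bead_count, fr$frame, sum)
    free[as.integer(names(agg)) + 1L] <- as.integer(agg)
  }
  if (free[1] == 0)
    .bp_stop("beadphage_no_free_beads",
             "first frame has no free beads; per-bead normalization undefined")
  raw_ing <- free[1] - free
  nclamp <- sum(raw_ing < 0)
  if (nclamp > 0)
    message(sprintf("ingested count clamped at 0 on %d frame(s)", nclamp))
  ing <- pmax(raw_ing, 0L)
  sm <- movingSmooth(ing, window = window, method = method)
  cellCounts <- as.integer(rep_len(cellCounts, nFrames))
  perCell <- ifelse(cellCounts > 0, sm / cellCounts, NA_real_)
  perBead <- pmin(1, pmax(0, sm / free[1]))
  new("IngestionSeries", frame = frames,
      timeMin = frames * meta@frameInterval,
      freeBeads = free, ingestedBeads = as.integer(ing),
      smoothedIngested = sm, perCell = perCell, perBead = perBead,
      cellCount = cellCounts, smoothingWindow = as.integer(window))
}

#' Phagocytic capacity class
#'
#' Bands the per-cell ingested bead tally: 0 beads = no capacity, 1-10 =
#' low capacity, more than 10 = high capacity.
#'
#' @param beadsPerCell non-negative integer vector
#' @return factor with levels no < low < high
#' @export
capacityClass <- function(beadsPerCell) {
  if (any(!is.finite(beadsPerCell)) || any(beadsPerCell < 0) ||
      any(beadsPerCell != round(beadsPerCell)))
    .bp_stop("beadphage_bad_capacity_input",
             "beadsPerCell must be non-negative integers")
  cls <- ifelse(beadsPerCell == 0, "no",
                ifelse(beadsPerCell <= 10, "low", "high"))
  factor(cls, levels = c("no", "low", "high"), ordered = TRUE)
}

#' Per-cell capacity table from tracks
#'
#' For each motile (cell-proxy) track, the bead count of its conglomerate
#' at the last observation, with the capacity class. Reported alongside
#' the automated cell count so manual counts can be substituted.
#'
#' @param tracks motile track table (see [cellTracks()])
#' @param detections labelled detection table with `bead_count`
#' @return data.frame(track_id, beads, capacity_class)
#' @export
capacityTable <- function(tracks, detections) {
  if (is.null(tracks) || nrow(tracks) == 0)
    return(data.frame(track_id = integer(), beads = integer(),
                      capacity_class = character()))
  rows <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    dr <- tr$det_row[nrow(tr)]
    b <- detections$bead_count[dr]
    lb <- detections$label[dr]
    data.frame(track_id = tr$track_id[1],
               beads = if (identical(lb, "ingested")) as.integer(b) else 0L)
  })
  out <- do.call(rbind, rows)
  out$capacity_class <- as.character(capacityClass(out$beads))
  rownames(out) <- NULL
  out[order(out$track_id), ]
}
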