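#' Automatic bead threshold for a frame
#'
#' Places the dark-object cutoff halfway between a dark anchor and the
#' background median. The anchor is the median of the darkest pixels
#' (0.2% of the frame, floored at 25 pixels - a couple of bead
#' footprints), which sits in the bead tone whenever beads are present
#' even if they cover a vanishing fraction of the field. Unlike a global
#' Otsu split, this keeps dim cell bodies out of the bead mask when cells
#' occupy more area than beads do. Returns `NA` for a degenerate
#' (near-constant) frame.
#'
#' @param frame numeric matrix
#' @param darkQuantile fraction of the frame treated as the dark tail
#' @param fraction position of the cutoff between anchor and median
#' @return intensity threshold, or `NA` if the frame has no dark content
#' @export
autoBeadThreshold <- function(frame, darkQuantile = 0.002, fraction = 0.5) {
  bg <- stats::median(frame)
  k <- max(25, ceiling(darkQuantile * length(frame)))
  anchor <- stats::median(sort(as.vector(frame), partial = k)[seq_len(k)])
  spread <- diff(range(frame))
  if (spread == 0 || (bg - anchor) < 0.05 * spread) return(NA_real_)
  anchor + fraction * (bg - anchor)
}

#' Detect bead conglomerates in one frame
#'
#' Thresholds the frame for high-contrast dark objects, labels connected
#' components, removes components outside the `[minArea, maxArea]` size
#' window (artifact rejection), and measures each surviving component:
#' pixel-mean centroid (0-based x, y), area in px^2, mean brightness, and
#' the local contrast of its surrounding annulus. Labels and bead counts
#' are filled later by [classifyDetections()] and [countBeads()].
#'
#' @param frame numeric matrix
#' @param params a [DetectionParams-class]
#' @param frameIndex 0-based frame index recorded in the output
#' @return data.frame with columns frame, index, x, y, area, brightness,
#'   contrast, label (NA), bead_count (NA); zero rows if the frame is
#'   degenerate (a warning is issued) or nothing passes the filters
#' @export
detectConglomerates <- function(frame, params = detectionParams(),
                                frameIndex = 0L) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  empty <- data.frame(frame = integer(), index = integer(), x = numeric(),
                      y = numeric(), area = numeric(), brightness = numeric(),
                      contrast = numeric(), label = character(),
                      bead_count = integer(), stringsAsFactors = FALSE)
  thr <- params@beadContrastThreshold
  if (is.na(thr)) thr <- autoBeadThreshold(frame)
  if (is.na(thr)) {
    warning("degenerate frame (no dark content): no detections")
    return(empty)
  }
  mask <- frame < thr
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  nlab <- max(lab)
  if (nlab == 0) return(empty)
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  keep <- which(areas >= params@minArea & areas <= params@maxArea)
  if (!length(keep)) return(empty)

  rng <- diff(range(frame))
  pix <- which(lab > 0)
  by_comp <- split(pix, lab[pix])[as.character(keep)]
  rows <- lapply(by_comp, function(idx) {
    rr <- (idx - 1L) %% nrow(frame) + 1L
    cc <- (idx - 1L) %/% nrow(frame) + 1L
    bright <- mean(frame[idx])
    if (!is.na(params@cellBrightnessThreshold) &&
        bright > params@cellBrightnessThreshold) return(NULL)
    contrast <- annulusContrastCpp(frame, rr, cc,
                                   params@neighborhoodRadius, rng)
    data.frame(frame = frameIndex, index = NA_integer_,
               x = mean(cc) - 1, y = mean(rr) - 1,
               area = as.numeric(length(idx)), brightness = bright,
               contrast = contrast, label = NA_character_,
               bead_count = NA_integer_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$y, out$x), , drop = FALSE]
  out$index <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  out
}

#' Build the cell-position mask for one frame
#'
#' The union of disks of `dilationRadius` around each tracked object's
#' position at the given frame. Tracks stand in for the phagocytosing cells
#' themselves (phase contrast is too weak to segment the cells directly),
#' so callers normally pass only the motile tracks, e.g. via
#' [cellTracks()]. No tracks gives an all-false mask.
#'
#' @param tracks track table (columns track_id, frame, x, y)
#' @param frameIndex 0-based frame
#' @param dim c(rows, cols) of the frame
#' @param dilationRadius disk radius in px
#' @return logical matrix
#' @export
buildCellMask <- function(tracks, frameIndex, dim, dilationRadius = 15) {
  mask <- matrix(FALSE, dim[1], dim[2])
  if (is.null(tracks) || nrow(tracks) == 0) return(mask)
  at <- tracks[tracks$frame == frameIndex, , drop = FALSE]
  if (nrow(at) == 0) return(mask)
  r <- ceiling(dilationRadius)
  for (i in seq_len(nrow(at))) {
    # 0-based centroid -> 1-based raster indices
    cx <- at$x[i] + 1; cy <- at$y[i] + 1
    rows <- max(1, floor(cy - r)):min(dim[1], ceiling(cy + r))
    cols <- max(1, floor(cx - r)):min(dim[2], ceiling(cx + r))
    dy <- rows - cy; dx <- cols - cx
    disk <- outer(dy^2, dx^2, "+") <= dilationRadius^2
    mask[rows, cols] <- mask[rows, cols] | disk
  }
  mask
}

#' Select the motile (cell-proxy) tracks
#'
#' Keeps the motile segment of every track that behaves like a migrating
#' cell. Ingested conglomerates ride on migrating cells and move
#' continuously; free beads only oscillate around their anchor, and a bead
#' briefly displaced by a passing cell moves for a few frames only. A
#' track therefore qualifies when, after trimming its stationary prefix
#' (a track can begin as a free bead that is later ingested and carried
#' off - movement evidence of a cell starts at the motion onset), its
#' maximum excursion from the segment start reaches `minDisplacement` px
#' and its median per-frame step sustains `minStep` px. Excursion rather
#' than end-to-end displacement is used because a migrating cell may loop
#' back to its starting point; an oscillating bead never leaves its
#' anchor's neighbourhood at all. The selected segments are what cell
#' masks and per-frame cell counts derive from.
#'
#' @param tracks track table
#' @param minDisplacement maximum excursion in px (default from
#'   [detectionParams()])
#' @param minStep median per-frame step in px
#' @param onsetWindow observations over which the onset of sustained
#'   motion is assessed
#' @param minSegment minimum observations in the motile segment; a brief
#'   push burst cannot reach it
#' @return track table restricted to the motile segments
#' @export
cellTracks <- function(tracks, minDisplacement = 5, minStep = 0.5,
                       onsetWindow = 5, minSegment = 15) {
  if (is.null(tracks) || nrow(tracks) == 0) return(tracks)
  segs <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    # Iteratively trim until the segment begins with sustained, jump-free
    # motion. A track can begin as a resting bead that an ingestion event
    # turns into a carried conglomerate (the linker bridges one large
    # jump from the anchor to the cell), and a track orphaned by a bead
    # displacement can chain through several such jumps before settling
    # on a moving conglomerate; each pass cuts one stationary stretch or
    # stitch jump off the front.
    repeat {
      n <- nrow(tr)
      if (n < max(2, minSegment)) return(NULL)
      steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / diff(tr$frame)
      w <- min(onsetWindow, length(steps))
      # a window counts as moving when its steps sustain minStep (median,
      # so a single displacement burst does not qualify) AND either it
      # translates as a whole or its steps are unambiguously stride-sized
      # (2x threshold, as a cell turning in place still strides at full
      # speed). Quantized detection jitter can fluke past minStep but
      # produces neither net displacement nor stride-sized medians.
      moving <- vapply(seq_len(length(steps) - w + 1), function(i) {
        med <- stats::median(steps[i:(i + w - 1)])
        med >= minStep &&
          (med >= 2 * minStep ||
             sqrt((tr$x[i + w] - tr$x[i])^2 +
                    (tr$y[i + w] - tr$y[i])^2) >= 3 * minStep)
      }, logical(1))
      if (!any(moving)) return(NULL)
      o <- which(moving)[1]
      win <- steps[o:(o + w - 1)]
      jump <- max(win) >= 3 * stats::median(win) && max(win) >= 2 * minStep
      if (o == 1 && !jump) break             # starts with clean motion
      onset <- if (jump) o + which.max(win)  # just past the stitch jump
      else {
        inwin <- which(win >= minStep)
        s <- o + (if (length(inwin)) inwin[1] - 1L else 0L)
        if (s > 1 && steps[s - 1] < minStep) s + 1L else s
      }
      if (onset <= 1) break                  # cannot trim further
      tr <- tr[onset:n, , drop = FALSE]
    }
    n <- nrow(tr)
    steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / diff(tr$frame)
    excursion <- max(sqrt((tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2))
    if (excursion >= minDisplacement && stats::median(steps) >= minStep) tr
    else NULL
  })
  out <- do.call(rbind, segs)
  if (is.null(out))
    return(tracks[0, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Classify detections as free or ingested
#'
#' A conglomerate is labelled `ingested` when its centroid falls inside the
#' cell mask (coincidence with a cell position) or when the contrast of its
#' surrounding annulus reaches `ingestionContrastThreshold` (cell borders
#' show stronger contrast than empty substrate, so a conglomerate with a
#' quiet surrounding is likely a free bead). The two criteria are combined
#' by OR. Otherwise the label is `free`.
#'
#' @param detections detection table for one frame (from
#'   [detectConglomerates()])
#' @param mask logical cell mask for the same frame
#' @param params a [DetectionParams-class]
#' @return the detection table with `label` filled
#' @export
classifyDetections <- function(detections, mask, params = detectionParams()) {
  if (nrow(detections) == 0) return(detections)
  ri <- round(detections$y) + 1
  ci <- round(detections$x) + 1
  if (any(ri < 1 | ri > nrow(mask) | ci < 1 | ci > ncol(mask)))
    .bp_stop("beadphage_corrupt_detection",
             "detection centroid outside image bounds")
  inMask <- mask[cbind(ri, ci)]
  highContrast <- detections$contrast >= params@ingestionContrastThreshold
  detections$label <- ifelse(inMask | highContrast, "ingested", "free")
  detections
}
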