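#' @useDynLib beadphage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.bp_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "beadphage_error")))
}

#' Acquisition metadata for a time-lapse sequence
#'
#' Holds the physical calibration of a recording: the time between frames,
#' the pixel scale of the optics and the total duration. Defaults match a
#' live-cell incubator microscope with a 4x objective imaging every 3.5
#' minutes for 24 hours at roughly 1.15 micrometres per pixel.
#'
#' @slot frameInterval minutes between consecutive frames
#' @slot pixelScale micrometres per pixel
#' @slot duration total recording length in minutes
#' @slot objectiveLabel free-text objective description
#' @export
setClass("AcquisitionMeta",
  representation(frameInterval = "numeric", pixelScale = "numeric",
                 duration = "numeric", objectiveLabel = "character"),
  validity = function(object) {
    if (length(object@frameInterval) != 1 || !is.finite(object@frameInterval) ||
        object@frameInterval <= 0)
      return("frameInterval must be a single positive number")
    if (length(object@pixelScale) != 1 || !is.finite(object@pixelScale) ||
        object@pixelScale <= 0)
      return("pixelScale must be a single positive number")
    if (length(object@duration) != 1 || !is.finite(object@duration) ||
        object@duration < object@frameInterval)
      return("duration must be >= frameInterval")
    TRUE
  })

#' @param frameInterval minutes per frame (default 3.5)
#' @param pixelScale micrometres per pixel (default 1.15)
#' @param duration total minutes (default 1440, i.e. 24 h)
#' @param objectiveLabel free text
#' @return an `AcquisitionMeta` object
#' @rdname AcquisitionMeta-class
#' @export
acquisitionMeta <- function(frameInterval = 3.5, pixelScale = 1.15,
                            duration = 1440, objectiveLabel = "4x") {
  new("AcquisitionMeta", frameInterval = frameInterval,
      pixelScale = pixelScale, duration = duration,
      objectiveLabel = objectiveLabel)
}

#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))

#' @rdname AcquisitionMeta-class
#' @param x object
#' @export
setMethod("frameInterval", "AcquisitionMeta", function(x) x@frameInterval)
#' @rdname AcquisitionMeta-class
#' @export
setMethod("pixelScale", "AcquisitionMeta", function(x) x@pixelScale)

setMethod("show", "AcquisitionMeta", function(object) {
  cat(sprintf(
    "AcquisitionMeta: %.3g min/frame, %.3g um/px, %.5g min total (%s)\n",
    object@frameInterval, object@pixelScale, object@duration,
    object@objectiveLabel))
})

#' An ordered grayscale time-lapse sequence
#'
#' Frames are numeric matrices indexed `[row, col]` with the raster origin at
#' the top-left corner; x runs rightwards along columns, y downwards along
#' rows, both 0-based. Centroids and track coordinates reported by the
#' package use this convention throughout. All frames share dimensions and
#' carry finite, non-negative intensities.
#'
#' @slot frames list of numeric matrices, one per frame, acquisition order
#' @slot meta an [AcquisitionMeta-class] object
#' @export
setClass("VideoSequence",
  representation(frames = "list", meta = "AcquisitionMeta"),
  validity = function(object) {
    if (length(object@frames) < 1) return("a sequence needs at least 1 frame")
    d <- dim(object@frames[[1]])
    for (i in seq_along(object@frames)) {
      f <- object@frames[[i]]
      if (!is.matrix(f) || !is.numeric(f))
        return(sprintf("frame %d is not a numeric matrix", i))
      if (!identical(dim(f), d))
        return(sprintf("frame %d dimensions differ from frame 1", i))
      if (anyNA(f) || any(!is.finite(f)) || any(f < 0))
        return(sprintf("frame %d has non-finite or negative intensities", i))
    }
    TRUE
  })

#' @param frames list of numeric matrices
#' @param meta an `AcquisitionMeta`
#' @rdname VideoSequence-class
#' @export
videoSequence <- function(frames, meta = acquisitionMeta()) {
  new("VideoSequence", frames = frames, meta = meta)
}

#' @rdname VideoSequence-class
#' @param x a `VideoSequence`
#' @export
setMethod("length", "VideoSequence", function(x) length(x@frames))

#' @rdname VideoSequence-class
#' @export
setMethod("dim", "VideoSequence", function(x) dim(x@frames[[1]]))

#' @rdname VideoSequence-class
#' @param i frame number (1-based)
#' @export
setMethod("[[", "VideoSequence", function(x, i) x@frames[[i]])

#' Frame timestamps in minutes
#'
#' Timestamp of frame `i` (0-based index) is `index * frameInterval`.
#' @param x a `VideoSequence`
#' @return numeric vector of minutes, one per frame
#' @export
frameTimes <- function(x) {
  stopifnot(is(x, "VideoSequence"))
  (seq_along(x@frames) - 1) * x@meta@frameInterval
}

#' @export
setGeneric("sequenceMeta", function(x) standardGeneric("sequenceMeta"))
#' @rdname VideoSequence-class
#' @export
setMethod("sequenceMeta", "VideoSequence", function(x) x@meta)

setMethod("show", "VideoSequence", function(object) {
  d <- dim(object)
  cat(sprintf("VideoSequence: %d frames of %dx%d px\n",
              length(object), d[1], d[2]))
  show(object@meta)
})

#' Detection parameters
#'
#' Thresholds governing conglomerate detection and the free-vs-ingested
#' classification. Beads are high-contrast dark objects, cells dim
#' low-contrast regions; detection thresholds on darkness and size, then a
#' size filter removes artifacts. Area bounds default to the physical bead
#' size: `minArea` is 40% of the raster area of one 4.5 um bead at the
#' configured pixel scale and `maxArea` is 60 bead areas.
#'
#' `beadContrastThreshold` and `cellBrightnessThreshold` default to `NA`,
#' meaning they are derived per frame: the bead threshold is placed halfway
#' between a dark anchor (the 0.2% intensity quantile, i.e. the bead tone)
#' and the background median, which keeps dim cell bodies out of the bead
#' mask even when cells cover more area than beads.
#'
#' @slot beadContrastThreshold absolute intensity cutoff for bead pixels
#'   (`NA` = per-frame automatic)
#' @slot cellBrightnessThreshold intensity above which a component is
#'   considered cell body rather than bead (`NA` = automatic)
#' @slot minArea,maxArea component area bounds in px^2
#' @slot neighborhoodRadius px gap between a component and its local-contrast
#'   annulus
#' @slot ingestionContrastThreshold dimensionless local-contrast cutoff for
#'   the surrounding-contrast ingestion criterion
#' @slot maskDilationRadius px radius of the disk drawn around each tracked
#'   cell position when building the cell mask
#' @slot minCellDisplacement px of net track displacement above which a track
#'   is treated as a (motile) cell when building the mask
#' @slot minCellStep px median per-frame step a track must sustain to count
#'   as a cell (separates migrating conglomerates from jittering or briefly
#'   displaced free beads)
#' @export
setClass("DetectionParams",
  representation(beadContrastThreshold = "numeric",
                 cellBrightnessThreshold = "numeric",
                 minArea = "numeric", maxArea = "numeric",
                 neighborhoodRadius = "numeric",
                 ingestionContrastThreshold = "numeric",
                 maskDilationRadius = "numeric",
                 minCellDisplacement = "numeric",
                 minCellStep = "numeric"),
  validity = function(object) {
    if (!(object@minArea > 0 && object@maxArea > object@minArea))
      return("need 0 < minArea < maxArea")
    if (object@neighborhoodRadius <= 0 || object@ingestionContrastThreshold <= 0 ||
        object@maskDilationRadius <= 0)
      return("radii and thresholds must be positive")
    TRUE
  })

#' @param pixelScale um per px used to anchor area defaults
#' @param beadDiameter bead diameter in um (Dynabeads M-450: 4.5)
#' @param beadContrastThreshold,cellBrightnessThreshold,minArea,maxArea,neighborhoodRadius,ingestionContrastThreshold,maskDilationRadius,minCellDisplacement,minCellStep see slots
#' @rdname DetectionParams-class
#' @export
detectionParams <- function(pixelScale = 1.15, beadDiameter = 4.5,
                            beadContrastThreshold = NA_real_,
                            cellBrightnessThreshold = NA_real_,
                            minArea = NULL, maxArea = NULL,
                            neighborhoodRadius = 3,
                            ingestionContrastThreshold = 0.08,
                            maskDilationRadius = 15,
                            minCellDisplacement = 5,
                            minCellStep = 0.5) {
  beadArea <- pi * (beadDiameter / 2 / pixelScale)^2
  if (is.null(minArea)) minArea <- 0.4 * beadArea
  if (is.null(maxArea)) maxArea <- 60 * beadArea
  new("DetectionParams",
      beadContrastThreshold = beadContrastThreshold,
      cellBrightnessThreshold = cellBrightnessThreshold,
      minArea = minArea, maxArea = maxArea,
      neighborhoodRadius = neighborhoodRadius,
      ingestionContrastThreshold = ingestionContrastThreshold,
      maskDilationRadius = maskDilationRadius,
      minCellDisplacement = minCellDisplacement,
      minCellStep = minCellStep)
}

setMethod("show", "DetectionParams", function(object) {
  cat(sprintf(
    "DetectionParams: area [%.1f, %.1f] px^2, annulus gap %g px, ingestion contrast >= %g\n",
    object@minArea, object@maxArea, object@neighborhoodRadius,
    object@ingestionContrastThreshold))
})

#' Tracking parameters
#'
#' @slot maxLinkDistance px an object may travel between consecutive frames
#' @slot maxGap frames an object may vanish before its track terminates
#' @slot minTrackLength minimum observations for a track to be kept
#' @export
setClass("TrackingParams",
  representation(maxLinkDistance = "numeric", maxGap = "numeric",
                 minTrackLength = "numeric"),
  validity = function(object) {
    if (object@maxLinkDistance <= 0 || object@maxGap < 0)
      return("maxLinkDistance must be positive, maxGap non-negative")
    if (object@minTrackLength < 2) return("minTrackLength must be >= 2")
    TRUE
  })

#' @param maxLinkDistance px per frame (default 20, about 23 um per 3.5 min)
#' @param maxGap frames (default 2)
#' @param minTrackLength frames (default 10)
#' @rdname TrackingParams-class
#' @export
trackingParams <- function(maxLinkDistance = 20, maxGap = 2,
                           minTrackLength = 10) {
  new("TrackingParams", maxLinkDistance = maxLinkDistance, maxGap = maxGap,
      minTrackLength = minTrackLength)
}

#' Size-brightness diagram of detected conglomerates
#'
#' Scatter of component area against mean brightness across all frames. The
#' density modes ("hotspots") sit at multiples of the single-bead area and
#' map areas to bead counts; detections beyond the last hotspot are counted
#' by area division (see [countBeads()]).
#'
#' @slot points data.frame with columns `area`, `brightness`
#' @slot hotspots strictly increasing modal areas for 1, 2, 3, ... beads
#' @slot outlierRule description of the rule applied beyond the last hotspot
#' @export
setClass("SizeBrightnessDiagram",
  representation(points = "data.frame", hotspots = "numeric",
                 outlierRule = "character"),
  validity = function(object) {
    h <- object@hotspots
    if (length(h) < 1 || h[1] <= 0) return("need at least one positive hotspot")
    if (length(h) > 1 && any(diff(h) <= 0))
      return("hotspots must be strictly increasing")
    TRUE
  })

#' @export
setGeneric("hotspots", function(x) standardGeneric("hotspots"))
#' @rdname SizeBrightnessDiagram-class
#' @param x a `SizeBrightnessDiagram`
#' @export
setMethod("hotspots", "SizeBrightnessDiagram", function(x) x@hotspots)

setMethod("show", "SizeBrightnessDiagram", function(object) {
  cat(sprintf("SizeBrightnessDiagram: %d points, hotspots [%s]\n",
              nrow(object@points),
              paste(sprintf("%.1f", object@hotspots), collapse = ", ")))
  cat(" beyond last hotspot:", object@outlierRule, "\n")
})

#' Per-frame free and cumulative ingested bead counts
#'
#' The free-bead count per frame, the cumulative ingested count obtained by
#' subtracting it from the free count of the first frame (which is assumed
#' to contain no ingested beads), a smoothed version, and the smoothed curve
#' normalized per cell and per initially available bead.
#'
#' @slot frame 0-based frame index
#' @slot timeMin minutes since start
#' @slot freeBeads free beads counted in the frame
#' @slot ingestedBeads `freeBeads[1] - freeBeads[t]`, clamped at 0
#' @slot smoothedIngested smoothed cumulative curve
#' @slot perCell smoothed curve divided by the per-frame cell count
#' @slot perBead smoothed curve divided by the initial free count, in [0,1]
#' @slot cellCount cells in the visual field per frame
#' @slot smoothingWindow frames in the smoothing window
#' @export
setClass("IngestionSeries",
  representation(frame = "integer", timeMin = "numeric",
                 freeBeads = "integer", ingestedBeads = "integer",
                 smoothedIngested = "numeric", perCell = "numeric",
                 perBead = "numeric", cellCount = "integer",
                 smoothingWindow = "integer"),
  validity = function(object) {
    n <- length(object@frame)
    lens <- c(length(object@timeMin), length(object@freeBeads),
              length(object@ingestedBeads), length(object@smoothedIngested),
              length(object@perCell), length(object@perBead),
              length(object@cellCount))
    if (any(lens != n)) return("all per-frame slots must have equal length")
    if (any(object@freeBeads < 0)) return("freeBeads must be >= 0")
    if (any(object@ingestedBeads < 0)) return("ingestedBeads clamped at >= 0")
    TRUE
  })

#' @rdname IngestionSeries-class
#' @param x an `IngestionSeries`
#' @param row.names,optional,... passed through
#' @export
setMethod("as.data.frame", "IngestionSeries",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(frame = x@frame, time_min = x@timeMin, free = x@freeBeads,
               ingested = x@ingestedBeads, smoothed = x@smoothedIngested,
               per_cell = x@perCell, per_bead = x@perBead,
               cells = x@cellCount)
  })

setMethod("show", "IngestionSeries", function(object) {
  n <- length(object@frame)
  cat(sprintf(
    "IngestionSeries: %d frames, free %d -> %d, ingested max %d (window %d)\n",
    n, object@freeBeads[1], object@freeBeads[n], max(object@ingestedBeads),
    object@smoothingWindow))
})

#' Synthetic scene configuration
#'
#' Describes a phase-contrast-like field: a bright background, dim motile
#' cell disks and dark bead disks. Cells follow a persistent random walk
#' (persistence 0 = direction redrawn every frame, 1 = ballistic) and
#' reflect at the field borders; free beads oscillate around fixed anchor
#' positions; scripted ingestion events transfer beads to a cell, after
#' which they move with it and are rendered as one conglomerate disk whose
#' area is the bead count times the single-bead area. Defaults follow the
#' assay conditions: 20 beads available per cell, 4.5 um beads.
#'
#' @slot fieldSize c(rows, cols) px
#' @slot nCells number of cells
#' @slot beadsPerCell free beads placed per cell (total = nCells*beadsPerCell
#'   unless `nBeads` is given)
#' @slot nBeads total free beads at frame 0
#' @slot nFrames frames to render
#' @slot beadRadiusPx bead radius in px (4.5 um diameter at the pixel scale)
#' @slot cellRadiusPx cell radius in px
#' @slot speed cell speed px/frame (scalar or one per cell)
#' @slot persistence direction persistence in [0,1]
#' @slot schedule data.frame(cell, frame, n_beads) of scripted ingestions
#' @slot noiseSd additive Gaussian noise sd (intensity units, frames in [0,1])
#' @slot backgroundLevel,beadIntensity,cellIntensity render tones in [0,1]
#' @slot beadJitterSd sd of the per-frame bead anchor oscillation, px
#' @slot seed integer seed; identical seeds give bit-identical output
#' @slot meta an [AcquisitionMeta-class]
#' @export
setClass("SceneConfig",
  representation(fieldSize = "integer", nCells = "integer",
                 beadsPerCell = "integer", nBeads = "integer",
                 nFrames = "integer", beadRadiusPx = "numeric",
                 cellRadiusPx = "numeric", speed = "numeric",
                 persistence = "numeric", schedule = "data.frame",
                 noiseSd = "numeric", backgroundLevel = "numeric",
                 beadIntensity = "numeric", cellIntensity = "numeric",
                 beadJitterSd = "numeric", seed = "integer",
                 meta = "AcquisitionMeta"),
  validity = function(object) {
    if (any(object@fieldSize < 32)) return("fieldSize must be >= 32 px")
    if (object@nFrames < 1) return("need at least one frame")
    if (object@nCells < 0 || object@nBeads < 0) return("counts must be >= 0")
    if (object@persistence < 0 || object@persistence > 1)
      return("persistence must be in [0,1]")
    s <- object@schedule
    if (nrow(s)) {
      if (!all(c("cell", "frame", "n_beads") %in% names(s)))
        return("schedule needs columns cell, frame, n_beads")
      if (any(s$cell < 1) || any(s$cell > object@nCells))
        return("schedule references a cell that does not exist")
      if (any(s$frame < 1) || any(s$frame >= object@nFrames))
        return("schedule frame out of range (1 .. nFrames-1)")
      if (any(s$n_beads < 1)) return("schedule n_beads must be >= 1")
      if (sum(s$n_beads) > object@nBeads)
        return("schedule demands more beads than exist in the field")
    }
    TRUE
  })

#' @param fieldSize,nCells,beadsPerCell,nBeads,nFrames,cellRadiusPx,speed,persistence,schedule,noiseSd,backgroundLevel,beadIntensity,cellIntensity,beadJitterSd,seed,meta see slots
#' @param beadDiameter bead diameter in um
#' @rdname SceneConfig-class
#' @export
sceneConfig <- function(fieldSize = c(256, 256), nCells = 10,
                        beadsPerCell = 20, nBeads = NULL, nFrames = 100,
                        beadDiameter = 4.5, cellRadiusPx = 13,
                        speed = 1.5, persistence = 0.8,
                        schedule = data.frame(cell = integer(),
                                              frame = integer(),
                                              n_beads = integer()),
                        noiseSd = 0.01, backgroundLevel = 0.85,
                        beadIntensity = 0.1, cellIntensity = 0.6,
                        beadJitterSd = 0.15, seed = 1,
                        meta = acquisitionMeta()) {
  if (is.null(nBeads)) nBeads <- nCells * beadsPerCell
  new("SceneConfig", fieldSize = as.integer(fieldSize),
      nCells = as.integer(nCells), beadsPerCell = as.integer(beadsPerCell),
      nBeads = as.integer(nBeads), nFrames = as.integer(nFrames),
      beadRadiusPx = beadDiameter / 2 / meta@pixelScale,
      cellRadiusPx = cellRadiusPx, speed = speed, persistence = persistence,
      schedule = schedule, noiseSd = noiseSd,
      backgroundLevel = backgroundLevel, beadIntensity = beadIntensity,
      cellIntensity = cellIntensity, beadJitterSd = beadJitterSd,
      seed = as.integer(seed), meta = meta)
}

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(
    "SceneConfig: %dx%d px, %d frames, %d cells, %d beads, %d scripted ingestions (seed %d)\n",
    object@fieldSize[1], object@fieldSize[2], object@nFrames, object@nCells,
    object@nBeads, nrow(object@schedule), object@seed))
})

#' Ground truth of a simulated scene
#'
#' The oracle for every downstream module: true cell positions per frame,
#' per-bead position and owner (0 = free, otherwise the ingesting cell id),
#' the derived free/ingested counts per frame, and final per-cell tallies.
#' Owners partition the beads, so `free + ingested = total` at every frame
#' in a closed field.
#'
#' @slot cells data.frame(frame, cell, x, y)
#' @slot beads data.frame(frame, bead, x, y, owner)
#' @slot counts data.frame(frame, free, ingested)
#' @slot perCell data.frame(cell, beads) final tallies
#' @export
setClass("SceneGroundTruth",
  representation(cells = "data.frame", beads = "data.frame",
                 counts = "data.frame", perCell = "data.frame"),
  validity = function(object) {
    cc <- object@counts
    if (nrow(cc) && length(unique(cc$free + cc$ingested)) != 1)
      return("free + ingested must be constant (closed field)")
    TRUE
  })

#' @export
setGeneric("trueCounts", function(x) standardGeneric("trueCounts"))
#' @rdname SceneGroundTruth-class
#' @param x a `SceneGroundTruth`
#' @export
setMethod("trueCounts", "SceneGroundTruth", function(x) x@counts)

setMethod("show", "SceneGroundTruth", function(object) {
  cat(sprintf(
    "SceneGroundTruth: %d frames, %d beads, %d cells; ingested at end: %d\n",
    nrow(object@counts), length(unique(object@beads$bead)),
    length(unique(object@cells$cell)),
    if (nrow(object@counts)) object@counts$ingested[nrow(object@counts)] else 0L))
})

#' Path models of a single track
#'
#' The raw centroid path, its robust-regression smoothed version, and the
#' Euclidean (start-to-end) displacement vector, together with the physical
#' calibration needed to express speeds in um/min.
#'
#' @slot raw n x 2 matrix of (x, y) px
#' @slot smoothed same dimensions, windowed robust linear fit per frame
#' @slot euclideanVector end point minus start point, px
#' @slot frames 0-based frame indices of the observations
#' @slot pixelScale um/px
#' @slot frameInterval min/frame
#' @export
setClass("PathSet",
  representation(raw = "matrix", smoothed = "matrix",
                 euclideanVector = "numeric", frames = "integer",
                 pixelScale = "numeric", frameInterval = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@raw), dim(object@smoothed)))
      return("raw and smoothed must have equal dimensions")
    ed <- sqrt(sum(object@euclideanVector^2))
    steps <- diff(object@raw)
    cum <- sum(sqrt(rowSums(steps^2)))
    if (ed > cum + 1e-9)
      return("euclidean displacement exceeds cumulative path length")
    TRUE
  })

setMethod("show", "PathSet", function(object) {
  cat(sprintf("PathSet: %d observations, euclidean %.2f px\n",
              nrow(object@raw), sqrt(sum(object@euclideanVector^2))))
})

#' Two-group comparison result
#'
#' Unpaired two-tailed t comparison with the significance bands used for
#' reporting: p < 0.05 "significant", p < 0.001 "very_significant",
#' otherwise "ns".
#'
#' @slot groupA,groupB the input values
#' @slot tStatistic,df,pValue test results
#' @slot band one of "ns", "significant", "very_significant"
#' @slot method "pooled" (Student) or "welch"
#' @export
setClass("GroupComparison",
  representation(groupA = "numeric", groupB = "numeric",
                 tStatistic = "numeric", df = "numeric", pValue = "numeric",
                 band = "character", method = "character"),
  validity = function(object) {
    if (object@pValue < 0 || object@pValue > 1) return("pValue must be in [0,1]")
    expected <- significanceBand(object@pValue)
    if (!identical(object@band, expected))
      return("band inconsistent with pValue thresholds")
    TRUE
  })

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison (%s): t = %.4f, df = %.4g, p = %.4g [%s]\n",
              object@method, object@tStatistic, object@df, object@pValue,
              object@band))
})
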