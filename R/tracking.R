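#' Link per-frame detections into tracks
#'
#' Frame-by-frame globally optimal one-to-one assignment between active
#' tracks and the next frame's detections, minimizing total squared
#' displacement. A track-detection pair is only linkable when their
#' distance is at most `maxLinkDistance * (gap + 1)`, where `gap` is the
#' number of frames the track has been unseen; the alternative of leaving
#' either side unmatched costs the corresponding gate squared, so links are
#' made exactly when they beat starting a new track. Unmatched detections
#' seed new tracks; tracks unseen for more than `maxGap` frames terminate;
#' tracks shorter than `minTrackLength` observations are discarded as
#' erroneous detections.
#'
#' Output is deterministic: detections are processed sorted by
#' (frame, y, x) and the assignment solver scans candidates in a fixed
#' order, so cost ties always resolve the same way.
#'
#' @param detections detection table (columns frame, x, y at minimum)
#' @param params a [TrackingParams-class]
#' @param frameInterval minutes per frame used for the `time_min` column
#' @return data.frame(track_id, frame, time_min, x, y, det_row) where
#'   `det_row` is the row of `detections` each observation came from
#' @export
linkTracks <- function(detections, params = trackingParams(),
                       frameInterval = 3.5) {
  out0 <- data.frame(track_id = integer(), frame = integer(),
                     time_min = numeric(), x = numeric(), y = numeric(),
                     det_row = integer())
  if (is.null(detections) || nrow(detections) == 0) return(out0)
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))

  ord <- order(detections$frame, detections$y, detections$x)
  det <- detections[ord, c("frame", "x", "y")]
  det$det_row <- ord

  maxd <- params@maxLinkDistance
  # active track state
  act_id <- integer(); act_x <- numeric(); act_y <- numeric()
  act_last <- integer()
  obs <- vector("list", 0)  # per track id: list of (frame, x, y, det_row)
  next_id <- 1L

  newTrack <- function(f, x, y, dr) {
    id <- next_id; next_id <<- next_id + 1L
    obs[[id]] <<- list(frame = f, x = x, y = y, det_row = dr)
    act_id <<- c(act_id, id); act_x <<- c(act_x, x); act_y <<- c(act_y, y)
    act_last <<- c(act_last, f)
  }
  appendObs <- function(id, f, x, y, dr) {
    o <- obs[[id]]
    obs[[id]] <<- list(frame = c(o$frame, f), x = c(o$x, x), y = c(o$y, y),
                       det_row = c(o$det_row, dr))
  }

  for (f in sort(unique(det$frame))) {
    # retire tracks unseen for more than maxGap frames
    alive <- (f - act_last) <= params@maxGap + 1L
    act_id <- act_id[alive]; act_x <- act_x[alive]; act_y <- act_y[alive]
    act_last <- act_last[alive]

    cur <- det[det$frame == f, , drop = FALSE]
    nD <- nrow(cur); nT <- length(act_id)
    if (nT == 0) {
      for (i in seq_len(nD)) newTrack(f, cur$x[i], cur$y[i], cur$det_row[i])
      next
    }
    gap <- f - act_last - 1L
    gate <- maxd * (gap + 1)
    dx <- outer(act_x, cur$x, "-"); dy <- outer(act_y, cur$y, "-")
    # cost is the squared per-frame displacement, so a track returning
    # after a gap competes on equal footing with a freshly seeded track
    d2raw <- dx^2 + dy^2
    d2 <- d2raw / (gap + 1)^2
    feas <- d2raw <= gate^2

    # The gating graph splits the global assignment into independent
    # connected components (almost all of size 1); each is solved exactly,
    # which is equivalent to one big matrix but orders of magnitude faster.
    parent <- seq_len(nT + nD)
    findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    pair_idx <- which(feas, arr.ind = TRUE)
    for (k in seq_len(nrow(pair_idx))) {
      a <- findp(pair_idx[k, 1]); b <- findp(nT + pair_idx[k, 2])
      if (a != b) parent[b] <- a
    }
    roots <- vapply(seq_len(nT + nD), findp, integer(1))

    linked_det <- rep(FALSE, nD)
    linkPair <- function(i, j) {
      id <- act_id[i]
      appendObs(id, f, cur$x[j], cur$y[j], cur$det_row[j])
      act_x[i] <<- cur$x[j]; act_y[i] <<- cur$y[j]; act_last[i] <<- f
      linked_det[j] <<- TRUE
    }
    for (rt in unique(roots)) {
      ti <- which(roots[seq_len(nT)] == rt)
      dj <- which(roots[nT + seq_len(nD)] == rt)
      if (!length(dj)) next           # track alone: stays unmatched
      if (!length(ti)) next           # detections alone: new tracks below
      if (length(ti) == 1 && length(dj) == 1) {
        if (d2[ti, dj] <= maxd^2) linkPair(ti, dj)
        next
      }
      # rectangular form: one dedicated no-link dummy column per track;
      # detections left unassigned seed new tracks afterwards
      a <- length(ti); b <- length(dj)
      BIG <- 4 * maxd^2 * (a + b) + 1e6
      cost <- d2[ti, dj, drop = FALSE]
      cost[!feas[ti, dj, drop = FALSE]] <- BIG
      m <- matrix(BIG, a, b + a)
      m[, seq_len(b)] <- cost
      m[cbind(seq_len(a), b + seq_len(a))] <- maxd^2
      asg <- solveAssignment(m)
      for (ii in seq_len(a)) {
        jj <- asg[ii]
        if (jj <= b && cost[ii, jj] < BIG) linkPair(ti[ii], dj[jj])
      }
    }
    for (j in which(!linked_det))
      newTrack(f, cur$x[j], cur$y[j], cur$det_row[j])
  }

  keep <- which(vapply(obs, function(o) length(o$frame), integer(1)) >=
                  params@minTrackLength)
  if (!length(keep)) return(out0)
  res <- do.call(rbind, lapply(keep, function(id) {
    o <- obs[[id]]
    data.frame(track_id = id, frame = o$frame,
               time_min = o$frame * frameInterval,
               x = o$x, y = o$y, det_row = o$det_row)
  }))
  # renumber track ids by first appearance for stable output
  first <- tapply(res$frame, res$track_id, min)
  remap <- rank(first * 1e9 + as.numeric(names(first)), ties.method = "first")
  res$track_id <- as.integer(remap[as.character(res$track_id)])
  res <- res[order(res$track_id, res$frame), ]
  rownames(res) <- NULL
  attr(res, "frameInterval") <- frameInterval
  res
}

.validateTracks <- function(tracks) {
  for (tr in split(tracks, tracks$track_id)) {
    if (any(diff(tr$frame[order(tr$frame)]) <= 0))
      .bp_stop("beadphage_bad_correction",
               sprintf("track %d has non-increasing frame indices",
                       tr$track_id[1]))
  }
  invisible(tracks)
}

#' Read a track-correction directive file (YAML)
#'
#' A correction file mirrors the human operator review step: a YAML list of
#' directives, each one of
#' \itemize{
#'   \item `action: split`, `track:`, `frame:` - split a track, observations
#'     from `frame` onwards forming a new track
#'   \item `action: merge`, `track_a:`, `track_b:` - concatenate b onto a
#'   \item `action: delete`, `track:` - remove a track
#'   \item `action: relabel`, `frame:`, `index:`, `track:` - reassign the
#'     detection identified by (frame, index) to the given track
#' }
#' @param path YAML file
#' @return list of directives
#' @export
readCorrections <- function(path) {
  if (!file.exists(path))
    .bp_stop("beadphage_missing_path", sprintf("no such file: %s", path))
  yaml::read_yaml(path)
}

#' Apply operator corrections to a track table
#'
#' Directives are applied in file order; each edit is checked to preserve
#' the track invariants (strictly increasing frames, known ids). The
#' provenance of the edits is recorded in the `corrections` attribute of
#' the result.
#'
#' @param tracks track table from [linkTracks()]
#' @param corrections directive list, e.g. from [readCorrections()]
#' @param detections optional detection table resolving `relabel` directives
#' @return corrected track table
#' @export
applyCorrections <- function(tracks, corrections, detections = NULL) {
  if (length(corrections) == 0) return(tracks)
  log <- character()
  for (k in seq_along(corrections)) {
    d <- corrections[[k]]
    act <- d$action
    if (is.null(act)) .bp_stop("beadphage_bad_correction",
                               sprintf("directive %d has no action", k))
    if (act == "delete") {
      .checkTrackId(tracks, d$track)
      tracks <- tracks[tracks$track_id != d$track, , drop = FALSE]
      log <- c(log, sprintf("delete track %d", d$track))
    } else if (act == "split") {
      .checkTrackId(tracks, d$track)
      sel <- tracks$track_id == d$track & tracks$frame >= d$frame
      if (!any(sel) || all(sel[tracks$track_id == d$track]))
        .bp_stop("beadphage_bad_correction",
                 sprintf("split of track %d at frame %d leaves an empty part",
                         d$track, d$frame))
      newid <- max(tracks$track_id) + 1L
      tracks$track_id[sel] <- newid
      log <- c(log, sprintf("split track %d at frame %d -> track %d",
                            d$track, d$frame, newid))
    } else if (act == "merge") {
      .checkTrackId(tracks, d$track_a); .checkTrackId(tracks, d$track_b)
      fa <- tracks$frame[tracks$track_id == d$track_a]
      fb <- tracks$frame[tracks$track_id == d$track_b]
      if (length(intersect(fa, fb)))
        .bp_stop("beadphage_bad_correction",
                 sprintf("merge of tracks %d and %d would duplicate frames",
                         d$track_a, d$track_b))
      tracks$track_id[tracks$track_id == d$track_b] <- d$track_a
      log <- c(log, sprintf("merge track %d into %d", d$track_b, d$track_a))
    } else if (act == "relabel") {
      if (is.null(detections))
        .bp_stop("beadphage_bad_correction",
                 "relabel directives require the detection table")
      hit <- which(detections$frame == d$frame & detections$index == d$index)
      if (length(hit) != 1)
        .bp_stop("beadphage_bad_correction",
                 sprintf("relabel: no detection (frame %d, index %d)",
                         d$frame, d$index))
      .checkTrackId(tracks, d$track)
      tracks <- tracks[!(tracks$track_id == d$track &
                           tracks$frame == d$frame), , drop = FALSE]
      fi <- attr(tracks, "frameInterval") %||% NA_real_
      add <- data.frame(track_id = d$track, frame = d$frame,
                        time_min = d$frame * fi,
                        x = detections$x[hit], y = detections$y[hit],
                        det_row = hit)
      tracks <- rbind(tracks[, names(add)], add)
      log <- c(log, sprintf("relabel detection (%d,%d) -> track %d",
                            d$frame, d$index, d$track))
    } else {
      .bp_stop("beadphage_bad_correction",
               sprintf("unknown correction action '%s'", act))
    }
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  .validateTracks(tracks)
  attr(tracks, "corrections") <- log
  tracks
}

.checkTrackId <- function(tracks, id) {
  if (is.null(id) || !id %in% tracks$track_id)
    .bp_stop("beadphage_bad_correction",
             sprintf("unknown track id: %s", as.character(id)))
}
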