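# Robust linear fit of a planar trajectory window, (x, y) ~ frame,
# evaluated at t0. Tukey bisquare via iteratively reweighted least squares
# (at most 50 iterations, coefficient tolerance 1e-8) with ONE weight per
# observation derived from the bivariate residual norm, so the smoother is
# exactly equivariant under rotations of the image plane (per-axis
# reweighting, as in a pair of independent rlm fits, is not). A window
# that ordinary least squares already fits to numerical precision
# (collinear points, as on a ballistic path) is a fixed point and is
# returned directly since no residual scale exists there.
.robustFitAt2D <- function(ts, xy, t0) {
  X <- cbind(1, ts)
  co <- qr.solve(X, xy)                    # OLS start, 2 x 2 coefficients
  res <- xy - X %*% co
  if (max(abs(res)) < 1e-8) return(co[1, ] + co[2, ] * t0)
  cc <- 4.685
  for (it in seq_len(50)) {
    r <- sqrt(rowSums(res^2))
    s <- stats::median(r) / 0.6745
    if (s < 1e-10) break
    u <- r / (cc * s)
    w <- ifelse(u < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 2) break              # pathological window: keep OLS
    sw <- sqrt(w)
    co_new <- tryCatch(qr.solve(X * sw, xy * sw), error = function(e) co)
    delta <- max(abs(co_new - co))
    co <- co_new
    res <- xy - X %*% co
    if (delta < 1e-8) break
  }
  co[1, ] + co[2, ] * t0
}

#' Smooth a centroid path by windowed robust linear regression
#'
#' For every frame, a robust line (Tukey bisquare, iteratively reweighted
#' least squares) of position versus frame is fitted over a centered
#' window of up to `window` frames and evaluated at that frame. The x and
#' y components share one weight per observation, computed from the
#' bivariate residual norm, which makes the smoother equivariant under
#' rotations of the image plane. The window shrinks near the path ends
#' but never below `minPoints` observations (or the whole path when
#' shorter). This removes stationary oscillations of the cell and tames
#' noisy centroid detections while leaving straight stretches untouched:
#' collinear input is a fixed point.
#'
#' @param raw n x 2 matrix of (x, y) positions, n >= 2
#' @param window window length in frames (default 20)
#' @param frames optional frame indices (default 0:(n-1)); used as the
#'   regression abscissa so gaps are respected
#' @param minPoints minimum window occupancy (default 5)
#' @return n x 2 matrix of smoothed positions
#' @export
smoothPath <- function(raw, window = 20, frames = NULL, minPoints = 5) {
  raw <- as.matrix(raw)
  n <- nrow(raw)
  if (n < 2)
    .bp_stop("beadphage_short_path", "smoothing needs at least 2 points")
  if (is.null(frames)) frames <- 0:(n - 1)
  half_lo <- floor((window - 1) / 2); half_hi <- ceiling((window - 1) / 2)
  minPoints <- min(minPoints, n)
  out <- matrix(NA_real_, n, 2)
  for (t in seq_len(n)) {
    lo <- max(1, t - half_lo); hi <- min(n, t + half_hi)
    # keep at least minPoints by extending toward the interior
    while (hi - lo + 1 < minPoints) {
      if (lo > 1) lo <- lo - 1 else hi <- hi + 1
    }
    out[t, ] <- .robustFitAt2D(frames[lo:hi], raw[lo:hi, , drop = FALSE],
                               frames[t])
  }
  colnames(out) <- c("x", "y")
  out
}

#' Euclidean (start-to-end) displacement of a path
#'
#' The effective path of the cell: its endpoint minus its starting point.
#' Used as the chemokinesis readout since no directional gradient is
#' applied.
#'
#' @param raw n x 2 matrix of positions in px
#' @param pixelScale um per px
#' @return displacement in um (0 for a single point or a closed loop)
#' @export
euclideanDistance <- function(raw, pixelScale = 1.15) {
  raw <- as.matrix(raw)
  if (nrow(raw) == 0)
    .bp_stop("beadphage_short_path", "empty path")
  if (nrow(raw) == 1) return(0)
  sqrt(sum((raw[nrow(raw), ] - raw[1, ])^2)) * pixelScale
}

#' Cumulative path length in px
#' @param xy n x 2 matrix
#' @return sum of stepwise Euclidean displacements
#' @export
pathLength <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Mean migration speed along a path
#'
#' Sum of stepwise Euclidean displacements divided by the elapsed time:
#' `n_steps * frameInterval` minutes (frame gaps count through the frame
#' indices when given), scaled to um/min.
#'
#' @param xy n x 2 matrix of positions in px (raw or smoothed)
#' @param meta an [AcquisitionMeta-class]
#' @param frames optional frame indices; elapsed frames default to n-1
#' @return speed in um/min
#' @export
meanSpeed <- function(xy, meta = acquisitionMeta(), frames = NULL) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2)
    .bp_stop("beadphage_short_path", "speed needs at least 2 points")
  nsteps <- if (is.null(frames)) nrow(xy) - 1
            else frames[length(frames)] - frames[1]
  pathLength(xy) / (nsteps * meta@frameInterval) * meta@pixelScale
}

#' Build the three path models for one track
#'
#' @param track observations of one track (columns frame, x, y), or an
#'   n x 2 matrix (frames then default to 0:(n-1))
#' @param meta an [AcquisitionMeta-class]
#' @param window smoothing window in frames
#' @return a [PathSet-class]
#' @export
pathSet <- function(track, meta = acquisitionMeta(), window = 20) {
  if (is.data.frame(track)) {
    track <- track[order(track$frame), ]
    raw <- cbind(x = track$x, y = track$y)
    frames <- as.integer(track$frame)
  } else {
    raw <- as.matrix(track)
    colnames(raw) <- c("x", "y")
    frames <- 0:(nrow(raw) - 1L)
  }
  sm <- smoothPath(raw, window = window, frames = frames)
  new("PathSet", raw = raw, smoothed = sm,
      euclideanVector = as.numeric(raw[nrow(raw), ] - raw[1, ]),
      frames = frames, pixelScale = meta@pixelScale,
      frameInterval = meta@frameInterval)
}

#' Per-track motion metrics
#'
#' Raw-path and smoothed-path mean speeds (um/min, with px/frame for
#' traceability) and the Euclidean displacement (um) for every track.
#'
#' @param tracks track table from [linkTracks()]
#' @param meta an [AcquisitionMeta-class]
#' @param window smoothing window in frames
#' @return data.frame(track_id, n_frames, raw_speed, smoothed_speed,
#'   euclidean_um, raw_px_per_frame, smoothed_px_per_frame)
#' @export
motionTable <- function(tracks, meta = acquisitionMeta(), window = 20) {
  if (is.null(tracks) || nrow(tracks) == 0)
    return(data.frame(track_id = integer(), n_frames = integer(),
                      raw_speed = numeric(), smoothed_speed = numeric(),
                      euclidean_um = numeric(),
                      raw_px_per_frame = numeric(),
                      smoothed_px_per_frame = numeric()))
  rows <- lapply(split(tracks, tracks$track_id), function(tr) {
    ps <- pathSet(tr, meta = meta, window = window)
    nsteps <- ps@frames[length(ps@frames)] - ps@frames[1]
    data.frame(track_id = tr$track_id[1], n_frames = nrow(ps@raw),
               raw_speed = meanSpeed(ps@raw, meta, ps@frames),
               smoothed_speed = meanSpeed(ps@smoothed, meta, ps@frames),
               euclidean_um = euclideanDistance(ps@raw, meta@pixelScale),
               raw_px_per_frame = pathLength(ps@raw) / nsteps,
               smoothed_px_per_frame = pathLength(ps@smoothed) / nsteps)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$track_id), ]
}

#' Group summary of a per-cell metric
#'
#' Mean, sample standard deviation and the 95% confidence interval of the
#' mean (Student t quantile, n-1 degrees of freedom) over the cells of a
#' visual field.
#'
#' @param values per-cell metric values, n >= 2
#' @return list(n, mean, sd, ci_lo, ci_hi)
#' @export
summarizeGroup <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2)
    .bp_stop("beadphage_too_few_values",
             "group summary needs at least 2 values")
  m <- mean(values); s <- stats::sd(values)
  hw <- stats::qt(0.975, n - 1) * s / sqrt(n)
  list(n = n, mean = m, sd = s, ci_lo = m - hw, ci_hi = m + hw)
}
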