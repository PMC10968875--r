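# All stochastic draws in a simulation flow from the config seed through
# R's global generator, saved and restored around the call, so identical
# configs give bit-identical sequences and ground truth.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0) else v / n
}

# Rejection-sample n points in [lo, hi]^2 with minimum pairwise spacing and
# outside given exclusion disks (centers, radius).
.placePoints <- function(n, lo, hi, spacing, excl_xy = NULL, excl_r = 0) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0
  for (tries in seq_len(n * 2000)) {
    if (placed == n) break
    p <- stats::runif(2, lo, hi)
    ok <- TRUE
    if (placed > 0) {
      d2 <- (pts[seq_len(placed), 1] - p[1])^2 +
            (pts[seq_len(placed), 2] - p[2])^2
      ok <- all(d2 >= spacing^2)
    }
    if (ok && !is.null(excl_xy) && nrow(excl_xy) > 0) {
      d2 <- (excl_xy[, 1] - p[1])^2 + (excl_xy[, 2] - p[2])^2
      ok <- all(d2 >= excl_r^2)
    }
    if (ok) { placed <- placed + 1; pts[placed, ] <- p }
  }
  if (placed < n)
    .bp_stop("beadphage_crowded_field",
             "could not place all objects with the requested spacing")
  pts
}

# Hard-edged disk: pixels whose supersampled coverage exceeds 1/2 take
# `value`. Used for beads so a rendered disk's pixel area matches the
# center-in-disk count (expectation pi*r^2 over subpixel positions).
.drawDiskHard <- function(mat, cx, cy, r, value) {
  .drawDisk(mat, cx, cy, r, value, hard = TRUE)
}

# Soft (coverage-blended) disk for cell bodies.
.drawDiskSoft <- function(mat, cx, cy, r, value) {
  .drawDisk(mat, cx, cy, r, value, hard = FALSE)
}

.ss_off <- (seq_len(3) - 2) / 3  # 3x3 subsamples per pixel

.drawDisk <- function(mat, cx, cy, r, value, hard) {
  # 0-based (x, y) center -> 1-based raster rows (y) and cols (x)
  rows <- max(1, floor(cy + 1 - r - 1)):min(nrow(mat), ceiling(cy + 1 + r + 1))
  cols <- max(1, floor(cx + 1 - r - 1)):min(ncol(mat), ceiling(cx + 1 + r + 1))
  if (!length(rows) || !length(cols)) return(mat)
  cov <- matrix(0, length(rows), length(cols))
  for (oy in .ss_off) for (ox in .ss_off) {
    dy <- (rows - 1 + oy) - cy
    dx <- (cols - 1 + ox) - cx
    cov <- cov + (outer(dy^2, dx^2, "+") <= r^2)
  }
  cov <- cov / 9
  sub <- mat[rows, cols, drop = FALSE]
  if (hard) sub[cov > 0.5] <- value
  else sub <- sub * (1 - cov) + value * cov
  mat[rows, cols] <- sub
  mat
}

#' Simulate a phase-contrast-like time-lapse scene
#'
#' Renders a bright background with dim motile cell disks and dark bead
#' disks, plus additive Gaussian noise, and returns the full ground truth.
#' Cells perform a persistent random walk (the heading is the
#' persistence-weighted previous heading plus a Gaussian turn, normalized)
#' and reflect at the field borders, never stacking on each other. Free
#' beads oscillate around fixed anchors; a free bead contacted by a
#' migrating cell is swept aside to a clear spot, so unscripted cell-bead
#' coincidence does not occur (physically, a bead reaching the cell front
#' would be either displaced or ingested, and ingestion is scripted).
#' At each scheduled ingestion the nearest free beads flip owner and move
#' with the cell from then on, rendered as a single conglomerate disk whose
#' area equals the bead count times the single-bead area. The field is
#' closed: no beads or cells enter or leave, so free + ingested is constant.
#'
#' Frames are quantized to the 16-bit intensity grid, matching the TIFF
#' writer, so a simulate/write/read cycle is bit-exact.
#'
#' @param config a [SceneConfig-class]
#' @return list(sequence = [VideoSequence-class],
#'   truth = [SceneGroundTruth-class])
#' @export
simulateScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  .with_seed(config@seed, .simulateSceneImpl(config))
}

.simulateSceneImpl <- function(config) {
  H <- config@fieldSize[1]; W <- config@fieldSize[2]
  nC <- config@nCells; nB <- config@nBeads; nF <- config@nFrames
  rB <- config@beadRadiusPx; rC <- config@cellRadiusPx
  # cell-bead exclusion: clears the cell border out of a free bead's
  # local-contrast annulus (annulus reaches ~7 px beyond the bead edge)
  excl <- rC + rB + 8
  speed <- rep_len(config@speed, max(nC, 1))

  cell_xy <- if (nC > 0)
    .placePoints(nC, rC + 2, min(H, W) - rC - 3, spacing = 2.5 * rC)
  else matrix(numeric(), 0, 2)
  heading <- if (nC > 0)
    t(apply(matrix(stats::rnorm(2 * nC), nC, 2), 1, .unit))
  else matrix(numeric(), 0, 2)
  spacing <- 2 * rB + 8  # keeps neighbours out of each other's annulus
  bead_anchor <- if (nB > 0)
    .placePoints(nB, rB + 2, min(H, W) - rB - 3,
                 spacing = spacing, excl_xy = cell_xy, excl_r = excl)
  else matrix(numeric(), 0, 2)
  owner <- rep(0L, nB)

  sched <- config@schedule
  frames <- vector("list", nF)
  gt_cells <- vector("list", nF); gt_beads <- vector("list", nF)
  gt_counts <- vector("list", nF)

  for (t in 0:(nF - 1)) {
    if (t > 0) {
      # cell steps. Cells are adherent and do not stack: a cell whose
      # step would bring it within contact range of a neighbour steers
      # around it (smallest heading rotation whose landing spot is clear)
      # rather than stopping, so cells keep striding even in a crowd and
      # two conglomerates can never merge into one detection.
      minsep <- 2.2 * rC
      for (i in seq_len(nC)) {
        g <- .unit(stats::rnorm(2))
        heading[i, ] <- .unit(config@persistence * heading[i, ] +
                                (1 - config@persistence) * g)
        others <- cell_xy[setdiff(seq_len(nC), i), , drop = FALSE]
        stepTo <- function(h) {
          p <- cell_xy[i, ] + speed[i] * h
          lims <- c(W, H)
          refl <- h
          for (a in 1:2) {
            lo <- rC; hi <- lims[a] - 1 - rC
            if (p[a] < lo) { p[a] <- 2 * lo - p[a]; refl[a] <- -refl[a] }
            if (p[a] > hi) { p[a] <- 2 * hi - p[a]; refl[a] <- -refl[a] }
          }
          list(p = p, h = refl)
        }
        placed <- FALSE
        for (rot_deg in c(0, as.vector(rbind(seq(15, 180, 15),
                                             -seq(15, 180, 15))))) {
          a <- rot_deg * pi / 180
          h <- c(cos(a) * heading[i, 1] - sin(a) * heading[i, 2],
                 sin(a) * heading[i, 1] + cos(a) * heading[i, 2])
          cand <- stepTo(h)
          clear <- !nrow(others) ||
            all((others[, 1] - cand$p[1])^2 +
                  (others[, 2] - cand$p[2])^2 >= minsep^2)
          if (clear) {
            cell_xy[i, ] <- cand$p
            heading[i, ] <- cand$h
            placed <- TRUE
            break
          }
        }
        # fully enclosed (rare): hold position this frame
        if (!placed) heading[i, ] <- .unit(stats::rnorm(2))
      }
      # A free bead contacted by an advancing cell is swept aside in a
      # single relocation to a clear spot elsewhere in the field. The two
      # halves of its history are both stationary, so a displaced bead can
      # never mimic a migrating cell, and free beads never overlap a cell
      # (a coincidence the classifier would have to count as ingested).
      if (nB > 0 && nC > 0) {
        free <- which(owner == 0L)
        for (b in free) {
          dC2 <- (cell_xy[, 1] - bead_anchor[b, 1])^2 +
                 (cell_xy[, 2] - bead_anchor[b, 2])^2
          if (all(dC2 >= excl^2)) next
          othersB <- bead_anchor[setdiff(seq_len(nB), b), , drop = FALSE]
          best <- NULL; bestScore <- -Inf
          for (try in 1:200) {
            p <- stats::runif(2, rB + 2, min(H, W) - rB - 3)
            dB2 <- if (nrow(othersB))
              min((othersB[, 1] - p[1])^2 + (othersB[, 2] - p[2])^2) else Inf
            dc2 <- min((cell_xy[, 1] - p[1])^2 + (cell_xy[, 2] - p[2])^2)
            score <- min(dB2 / spacing^2, dc2 / excl^2)
            if (score > bestScore) { bestScore <- score; best <- p }
            if (dB2 >= spacing^2 && dc2 >= excl^2) break
          }
          bead_anchor[b, ] <- best
        }
      }
      # scripted ingestions
      ev <- sched[sched$frame == t, , drop = FALSE]
      for (e in seq_len(nrow(ev))) {
        ci <- ev$cell[e]; k <- ev$n_beads[e]
        free <- which(owner == 0L)
        if (length(free) < k)
          .bp_stop("beadphage_schedule_overdraw",
                   sprintf("frame %d: schedule demands %d beads, %d free",
                           t, k, length(free)))
        dv <- sweep(bead_anchor[free, , drop = FALSE], 2, cell_xy[ci, ])
        take <- free[order(rowSums(dv^2))[seq_len(k)]]
        owner[take] <- ci
      }
    }

    jitter <- if (nB > 0)
      matrix(stats::rnorm(2 * nB, sd = config@beadJitterSd), nB, 2)
    else matrix(numeric(), 0, 2)
    bead_xy <- bead_anchor + jitter
    ingested_mask <- owner != 0L
    if (any(ingested_mask)) bead_xy[ingested_mask, ] <-
      cell_xy[owner[ingested_mask], , drop = FALSE]

    # ground truth before rendering noise
    if (nC > 0)
      gt_cells[[t + 1]] <- data.frame(frame = t, cell = seq_len(nC),
                                      x = cell_xy[, 1], y = cell_xy[, 2])
    if (nB > 0)
      gt_beads[[t + 1]] <- data.frame(frame = t, bead = seq_len(nB),
                                      x = bead_xy[, 1], y = bead_xy[, 2],
                                      owner = owner)
    gt_counts[[t + 1]] <- data.frame(frame = t,
                                     free = sum(owner == 0L),
                                     ingested = sum(owner != 0L))

    img <- matrix(config@backgroundLevel, H, W)
    for (i in seq_len(nC))
      img <- .drawDiskSoft(img, cell_xy[i, 1], cell_xy[i, 2], rC,
                           config@cellIntensity)
    for (i in seq_len(nC)) {
      k <- sum(owner == i)
      if (k > 0)
        img <- .drawDiskHard(img, cell_xy[i, 1], cell_xy[i, 2],
                             rB * sqrt(k), config@beadIntensity)
    }
    fb <- which(owner == 0L)
    for (b in fb)
      img <- .drawDiskHard(img, bead_xy[b, 1], bead_xy[b, 2], rB,
                           config@beadIntensity)
    if (config@noiseSd > 0)
      img <- img + matrix(stats::rnorm(H * W, sd = config@noiseSd), H, W)
    img <- pmin(pmax(img, 0), 1)
    frames[[t + 1]] <- round(img * 65535) / 65535  # 16-bit grid
  }

  perCell <- data.frame(cell = seq_len(max(nC, 0)),
                        beads = vapply(seq_len(max(nC, 0)),
                                       function(i) sum(owner == i),
                                       integer(1)))
  truth <- new("SceneGroundTruth",
               cells = do.call(rbind, gt_cells) %||%
                 data.frame(frame = integer(), cell = integer(),
                            x = numeric(), y = numeric()),
               beads = do.call(rbind, gt_beads) %||%
                 data.frame(frame = integer(), bead = integer(),
                            x = numeric(), y = numeric(), owner = integer()),
               counts = do.call(rbind, gt_counts),
               perCell = perCell)
  list(sequence = videoSequence(frames, config@meta), truth = truth)
}

#' Deterministic library of named validation scenarios
#'
#' Seeded synthetic scenes exercising every analysis operator: static
#' beads, a single ballistic cell carrying a conglomerate, a staged
#' multi-cell ingestion scene, and a matched control / drug-like pair in
#' which the treated scene has reduced speed and ingestion rate. The
#' `"full"` level adds a Brownian crowd and the full-scale staged scene
#' (256 x 256 px, 200 frames, 10 cells, 200 beads).
#'
#' @param level "smoke" (5 scenarios, each at most 100 frames of
#'   256 x 256 px) or "full"
#' @param seed base seed; each scenario derives its own offset from it
#' @return named list of list(config, sequence, truth)
#' @export
fixtureSuite <- function(level = c("smoke", "full"), seed = 1) {
  level <- match.arg(level)
  cfgs <- list(
    static_beads = sceneConfig(fieldSize = c(128, 128), nCells = 0,
                               nBeads = 20, nFrames = 40, noiseSd = 0.005,
                               seed = seed),
    single_ballistic = sceneConfig(
      fieldSize = c(192, 192), nCells = 1, nBeads = 25, nFrames = 80,
      speed = 2, persistence = 1, noiseSd = 0.005,
      schedule = data.frame(cell = 1, frame = 4, n_beads = 3),
      seed = seed + 1),
    staged_ingestion = sceneConfig(
      fieldSize = c(256, 256), nCells = 4, nBeads = 80, nFrames = 100,
      speed = 1.2, persistence = 0.85, noiseSd = 0.01,
      schedule = data.frame(cell = c(1, 2, 3, 4, 1, 2),
                            frame = c(10, 20, 32, 44, 58, 70),
                            n_beads = c(2, 3, 2, 4, 3, 2)),
      seed = seed + 2),
    control = sceneConfig(
      fieldSize = c(224, 224), nCells = 4, nBeads = 80, nFrames = 60,
      speed = 1.8, persistence = 0.85, noiseSd = 0.01,
      schedule = data.frame(cell = c(1, 2, 3, 4, 1, 2, 3, 4),
                            frame = c(6, 10, 14, 18, 26, 32, 38, 44),
                            n_beads = c(3, 4, 3, 4, 4, 3, 4, 3)),
      seed = seed + 3),
    dsf_like = sceneConfig(
      fieldSize = c(224, 224), nCells = 4, nBeads = 80, nFrames = 60,
      speed = 0.7, persistence = 0.85, noiseSd = 0.01,
      schedule = data.frame(cell = c(1, 2, 3), frame = c(12, 24, 40),
                            n_beads = c(2, 1, 2)),
      seed = seed + 4))
  if (level == "full") {
    cfgs$brownian_crowd <- sceneConfig(
      fieldSize = c(256, 256), nCells = 6, nBeads = 90, nFrames = 120,
      speed = 1.5, persistence = 0.1, noiseSd = 0.01,
      schedule = data.frame(cell = 1:6, frame = seq(10, 60, by = 10),
                            n_beads = rep(2, 6)),
      seed = seed + 5)
    cfgs$staged_ingestion_full <- stagedIngestionConfig(seed = seed + 6)
  }
  lapply(cfgs, function(cf) c(list(config = cf), simulateScene(cf)))
}

#' The full-scale staged-ingestion validation scene
#'
#' 256 x 256 px, 200 frames, 10 cells, 200 beads, with ingestion events
#' scripted between frames 20 and 150 - the end-to-end recovery benchmark.
#'
#' @param seed integer seed
#' @return a [SceneConfig-class]
#' @export
stagedIngestionConfig <- function(seed = 1) {
  sceneConfig(
    fieldSize = c(256, 256), nCells = 10, nBeads = 200, nFrames = 200,
    beadsPerCell = 20, speed = 1.2, persistence = 0.85, noiseSd = 0.01,
    schedule = data.frame(
      cell = c(1:10, c(2, 4, 6, 8, 10)),
      frame = c(seq(20, 110, by = 10), c(120, 128, 135, 142, 150)),
      n_beads = c(2, 3, 2, 4, 3, 2, 3, 4, 2, 3, 2, 3, 2, 3, 2)),
    seed = seed)
}
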