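rB <- 4.5 / 2 / 1.15  # bead radius in px at the default pixel scale

test_that("a uniform frame yields no detections and a warning", {
  expect_warning(d <- detectConglomerates(matrix(0.5, 64, 64)),
                 "degenerate")
  expect_equal(nrow(d), 0)
})

test_that("disjoint dark disks are each detected with centroids within 1 px", {
  centers <- rbind(c(15.3, 20.7), c(40.0, 12.5), c(50.6, 50.1))
  fr <- diskFrame(c(64, 64), centers, radius = 3)
  d <- detectConglomerates(fr, detectionParams())
  expect_equal(nrow(d), 3)
  ord <- order(centers[, 2], centers[, 1])
  expect_lt(max(abs(d$x - centers[ord, 1])), 1)
  expect_lt(max(abs(d$y - centers[ord, 2])), 1)
})

test_that("components below the minimum area are filtered out", {
  centers <- rbind(c(20, 20), c(45, 45))
  fr <- diskFrame(c(64, 64), centers[1, , drop = FALSE], radius = 3)
  fr[46, 46] <- 0.1  # single dark pixel, far below min area
  d <- detectConglomerates(fr, detectionParams())
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 20), 1)
})

test_that("detection is equivariant under integer translations", {
  centers <- rbind(c(18.4, 22.6), c(40.2, 35.9))
  fr <- diskFrame(c(96, 96), centers, radius = rB)
  sh <- centers; sh[, 1] <- sh[, 1] + 7; sh[, 2] <- sh[, 2] + 11
  fr2 <- diskFrame(c(96, 96), sh, radius = rB)
  d1 <- detectConglomerates(fr); d2 <- detectConglomerates(fr2)
  expect_equal(nrow(d1), 2); expect_equal(nrow(d2), 2)
  expect_lt(max(abs(d2$x - d1$x - 7)), 0.5)
  expect_lt(max(abs(d2$y - d1$y - 11)), 0.5)
})

test_that("detection recovers all beads on a low-noise simulated field", {
  sim <- simulateScene(sceneConfig(nCells = 0, nBeads = 20, nFrames = 1,
                                   fieldSize = c(128, 128), noiseSd = 0.005,
                                   seed = 5))
  d <- detectConglomerates(sim$sequence[[1]])
  truth <- sim$truth@beads
  expect_equal(nrow(d), 20)       # recall and precision both 100%
  for (i in seq_len(nrow(d))) {
    dd <- sqrt((truth$x - d$x[i])^2 + (truth$y - d$y[i])^2)
    expect_lt(min(dd), 1)
  }
})

test_that("local contrast is non-negative, zero on constant surroundings, and matches a direct oracle", {
  fr <- diskFrame(c(48, 48), rbind(c(24, 24)), radius = 3)
  d <- detectConglomerates(fr)
  expect_equal(d$contrast, 0)  # flat background around the disk

  # put structure in the annulus and compare against a brute-force oracle
  fr2 <- fr
  fr2[18:19, ] <- 0.6
  d2 <- detectConglomerates(fr2)
  comp <- which(fr2 < 0.45)
  rr <- (comp - 1) %% 48 + 1; cc <- (comp - 1) %/% 48 + 1
  gap <- 3
  dmin <- matrix(Inf, 48, 48)
  for (k in seq_along(rr))
    dmin <- pmin(dmin, outer((1:48 - rr[k])^2, rep(1, 48)) +
                        outer(rep(1, 48), (1:48 - cc[k])^2))
  dmin <- sqrt(dmin); dmin[comp] <- 0
  ann <- dmin > gap & dmin <= gap + 2
  oracle <- sd(fr2[ann]) / diff(range(fr2))
  expect_equal(d2$contrast, oracle, tolerance = 1e-12)
  expect_gte(d2$contrast, 0)
})

test_that("cell masks are unions of disks around tracked positions", {
  expect_false(any(buildCellMask(NULL, 0, c(64, 64), 10)))
  tracks <- data.frame(track_id = 1, frame = 0, x = 50, y = 50)
  m <- buildCellMask(tracks, 0, c(100, 100), 10)
  expect_true(m[51, 51])              # centre (0-based 50,50)
  expect_true(m[51, 41]); expect_false(m[51, 39])
  in_disk <- which(m, arr.ind = TRUE)
  expect_true(all(((in_disk[, 1] - 51)^2 + (in_disk[, 2] - 51)^2) <= 100 + 1e-9))

  two <- rbind(tracks, data.frame(track_id = 2, frame = 0, x = 58, y = 50))
  m2 <- buildCellMask(two, 0, c(100, 100), 10)
  expect_equal(sum(m2), sum(buildCellMask(tracks, 0, c(100, 100), 10) |
                              buildCellMask(two[2, ], 0, c(100, 100), 10)))
})

test_that("classification follows mask coincidence OR surrounding contrast", {
  fr <- diskFrame(c(64, 64), rbind(c(20, 20), c(45, 45)), radius = 3)
  d <- detectConglomerates(fr)
  mask <- matrix(FALSE, 64, 64); mask[15:25, 15:25] <- TRUE
  lab <- classifyDetections(d, mask, detectionParams())
  expect_equal(lab$label[lab$x < 30], "ingested")  # centroid inside mask
  expect_equal(lab$label[lab$x > 30], "free")      # quiet surroundings
  # empty mask, uniform surroundings: everything free
  lab2 <- classifyDetections(d, matrix(FALSE, 64, 64), detectionParams())
  expect_true(all(lab2$label == "free"))
  # labels partition the detections
  expect_equal(sum(lab$label == "free") + sum(lab$label == "ingested"),
               nrow(lab))
})

test_that("a centroid outside the image is rejected as corrupt", {
  d <- data.frame(frame = 0, index = 0, x = 500, y = 5, area = 10,
                  brightness = 0.1, contrast = 0, label = NA, bead_count = NA)
  expect_error(classifyDetections(d, matrix(FALSE, 64, 64)),
               class = "beadphage_corrupt_detection")
})

test_that("high surrounding contrast marks a conglomerate ingested without a mask", {
  # bead just inside a dim cell disk: annulus crosses the cell border
  frame <- diskFrame(c(64, 64), rbind(c(32, 32)), radius = 6, tone = 0.6)
  bead <- outer((0:63 - 32)^2, (0:63 - 30)^2, "+") <= 4  # (x=30, y=32)
  frame[bead] <- 0.1
  d <- detectConglomerates(frame)
  expect_equal(nrow(d), 1)
  lab <- classifyDetections(d, matrix(FALSE, 64, 64), detectionParams())
  expect_equal(lab$label, "ingested")
})
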