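test_that("a single steadily moving object yields one complete track", {
  pos <- lapply(1:50, function(f) cbind(10 + 2 * f, 20))
  tr <- linkTracks(detTable(pos), trackingParams())
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 50)
  expect_equal(tr$frame, 0:49)
  expect_equal(tr$time_min, (0:49) * 3.5)
})

test_that("well-separated objects keep their identities", {
  set.seed(11)
  start <- rbind(c(30, 30), c(150, 30), c(30, 150), c(150, 150))
  pos <- list()
  cur <- start
  for (f in 1:60) {
    cur <- cur + matrix(rnorm(8, sd = 2), 4, 2)
    pos[[f]] <- cur
  }
  tr <- linkTracks(detTable(pos), trackingParams())
  expect_equal(length(unique(tr$track_id)), 4)
  # identity: each track stays near its own starting corner
  for (id in unique(tr$track_id)) {
    t1 <- tr[tr$track_id == id, ]
    d0 <- sqrt((start[, 1] - t1$x[1])^2 + (start[, 2] - t1$y[1])^2)
    own <- which.min(d0)
    expect_true(all(sqrt((t1$x - start[own, 1])^2 +
                           (t1$y - start[own, 2])^2) < 60))
  }
})

test_that("an object absent beyond the gap limit starts a new track", {
  pos <- lapply(1:30, function(f) {
    if (f >= 12 && f <= 14) return(NULL)  # gone for maxGap + 1 = 3 frames
    cbind(50 + f, 50)
  })
  tr <- linkTracks(detTable(pos), trackingParams(maxGap = 2,
                                                 minTrackLength = 2))
  expect_equal(length(unique(tr$track_id)), 2)
  spans <- tapply(tr$frame, tr$track_id, range)
  expect_equal(sort(unname(vapply(spans, diff, numeric(1)))), c(10, 15))
})

test_that("an object absent within the gap limit keeps its track", {
  pos <- lapply(1:30, function(f) {
    if (f == 12) return(NULL)
    cbind(50 + f, 50)
  })
  tr <- linkTracks(detTable(pos), trackingParams())
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 29)
})

test_that("frame-to-frame matching agrees with brute-force enumeration", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    a <- cbind(runif(n, 10, 240), runif(n, 10, 240))
    b <- a + matrix(rnorm(2 * n, sd = 4), n, 2)
    det <- detTable(list(a, b))
    tr <- linkTracks(det, trackingParams(minTrackLength = 2))
    oracle <- bruteForceMatch(a, b)
    # cost of the links made by the tracker
    cost <- 0
    for (id in unique(tr$track_id)) {
      t1 <- tr[tr$track_id == id, ]
      if (nrow(t1) == 2)
        cost <- cost + sum((t1$x[2] - t1$x[1])^2 + (t1$y[2] - t1$y[1])^2)
    }
    # when every pair is linkable the tracker must reach the optimum
    if (length(unique(tr$track_id)) == n)
      expect_equal(cost, oracle$cost, tolerance = 1e-9)
  }
})

test_that("tracking output is deterministic across repeated runs", {
  set.seed(5)
  pos <- list(); cur <- cbind(runif(6, 20, 230), runif(6, 20, 230))
  for (f in 1:25) { cur <- cur + matrix(rnorm(12), 6, 2); pos[[f]] <- cur }
  det <- detTable(pos)
  t1 <- linkTracks(det, trackingParams())
  t2 <- linkTracks(det, trackingParams())
  expect_identical(t1, t2)
  # shuffled input rows give the same tracks (internal sort by frame, y, x)
  det2 <- det[sample(nrow(det)), ]
  t3 <- linkTracks(det2, trackingParams())
  expect_equal(t1[, c("track_id", "frame", "x", "y")],
               t3[, c("track_id", "frame", "x", "y")])
})

test_that("no detection is used by more than one track per frame", {
  set.seed(31)
  pos <- list(); cur <- cbind(runif(8, 20, 230), runif(8, 20, 230))
  for (f in 1:20) { cur <- cur + matrix(rnorm(16, sd = 3), 8, 2); pos[[f]] <- cur }
  tr <- linkTracks(detTable(pos), trackingParams(minTrackLength = 2))
  expect_false(any(duplicated(tr$det_row)))
  for (tid in unique(tr$track_id)) {
    t1 <- tr[tr$track_id == tid, ]
    expect_false(any(duplicated(t1$frame)))
    expect_true(all(diff(t1$frame) > 0))
  }
})

test_that("corrections apply in order and preserve track invariants", {
  pos <- lapply(1:20, function(f) rbind(c(10 + f, 10), c(100, 100 + f)))
  tr <- linkTracks(detTable(pos), trackingParams())
  expect_equal(length(unique(tr$track_id)), 2)

  expect_identical(applyCorrections(tr, list()), tr)

  del <- applyCorrections(tr, list(list(action = "delete", track = 2)))
  expect_false(2 %in% del$track_id)
  expect_equal(del[del$track_id == 1, c("frame", "x", "y")],
               tr[tr$track_id == 1, c("frame", "x", "y")])

  sp <- applyCorrections(tr, list(list(action = "split", track = 1,
                                       frame = 10)))
  expect_equal(length(unique(sp$track_id)), 3)
  newid <- setdiff(unique(sp$track_id), c(1, 2))
  expect_equal(sort(c(sp$frame[sp$track_id == 1],
                      sp$frame[sp$track_id == newid])),
               tr$frame[tr$track_id == 1])
  expect_true(all(sp$frame[sp$track_id == newid] >= 10))

  mg <- applyCorrections(sp, list(list(action = "merge", track_a = 1,
                                       track_b = newid)))
  expect_equal(mg[mg$track_id == 1, c("frame", "x", "y")],
               tr[tr$track_id == 1, c("frame", "x", "y")])

  expect_error(applyCorrections(tr, list(list(action = "delete", track = 99))),
               class = "beadphage_bad_correction")
  expect_error(applyCorrections(tr, list(list(action = "merge", track_a = 1,
                                              track_b = 2))),
               class = "beadphage_bad_correction")  # overlapping frames
})

test_that("correction files read from YAML drive the same edits", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- action: delete", "  track: 1"), f)
  cor <- readCorrections(f)
  pos <- lapply(1:15, function(f) rbind(c(10 + f, 10), c(100, 100 + f)))
  tr <- linkTracks(detTable(pos), trackingParams())
  out <- applyCorrections(tr, cor)
  expect_false(1 %in% out$track_id)
  expect_equal(attr(out, "corrections"), "delete track 1")
})
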