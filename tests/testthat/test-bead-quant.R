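test_that("hotspots are recovered at one, two and three bead areas", {
  set.seed(42)
  A <- 12
  areas <- c(rnorm(200, A, 0.05 * A), rnorm(80, 2 * A, 0.05 * 2 * A),
             rnorm(40, 3 * A, 0.05 * 3 * A))
  pts <- data.frame(area = areas, brightness = rnorm(320, 0.11, 0.005))
  dg <- fitSizeBrightness(pts)
  hs <- hotspots(dg)
  expect_equal(length(hs), 3)
  expect_equal(hs[1], A, tolerance = 0.05)
  expect_equal(hs[2], 2 * A, tolerance = 0.05)
  expect_equal(hs[3], 3 * A, tolerance = 0.05)
})

test_that("identical areas give a single hotspot and few points error out", {
  pts <- data.frame(area = rep(10, 20), brightness = rep(0.1, 20))
  dg <- fitSizeBrightness(pts)
  expect_equal(hotspots(dg), 10)
  expect_error(fitSizeBrightness(pts[1:9, ]),
               class = "beadphage_too_few_points")
})

test_that("bead counts use the nearest hotspot then the area-division rule", {
  set.seed(1)
  A <- 12
  pts <- data.frame(area = c(rnorm(100, A, 0.4), rnorm(40, 2 * A, 0.6),
                             rnorm(20, 3 * A, 0.8)),
                    brightness = rnorm(160, 0.11, 0.005))
  dg <- fitSizeBrightness(pts)
  a1 <- hotspots(dg)[1]
  expect_equal(countBeads(a1, dg), 1L)
  expect_equal(countBeads(c(a1, 2 * a1, 3 * a1), dg), 1:3)
  expect_equal(countBeads(5.1 * a1, dg), 5L)
  # outlier rule agrees with the brute-force oracle for 4..20 beads
  for (k in 4:20) {
    areas <- k * a1 * c(0.92, 1, 1.07)
    expect_equal(countBeads(areas, dg),
                 pmax(1L, as.integer(round(areas / a1))))
  }
})

test_that("ingestion series implements subtraction from the first frame", {
  # free 100 -> 60 with 20 cells: ingested 40, per-cell 2.0
  dets <- seriesDets(c(100, 80, 60))
  s <- ingestionSeries(dets, cellCounts = 20, window = 1)
  df <- as.data.frame(s)
  expect_equal(df$free, c(100, 80, 60))
  expect_equal(df$ingested, c(0, 20, 40))
  expect_equal(df$per_cell[3], 2)
  expect_equal(df$per_bead, c(0, 0.2, 0.4))
  # constant free count: ingested identically zero
  s0 <- ingestionSeries(seriesDets(rep(7, 5)), cellCounts = 1)
  expect_true(all(as.data.frame(s0)$ingested == 0))
})

test_that("negative ingested counts are clamped with a message", {
  dets <- seriesDets(c(10, 12, 9))  # detection noise pushed free above free[0]
  expect_message(s <- ingestionSeries(dets, cellCounts = 1, window = 1),
                 "clamped")
  expect_equal(as.data.frame(s)$ingested, c(0, 0, 1))
})

test_that("an empty first frame makes per-bead normalization fail loudly", {
  dets <- data.frame(frame = 1L, label = "free", bead_count = 5L)
  expect_error(ingestionSeries(dets, cellCounts = 1, nFrames = 2),
               class = "beadphage_no_free_beads")
})

test_that("the smoother is mean-preserving on constant-ended series and bounded", {
  x <- c(rep(0, 6), 0, 2, 5, 9, 9, rep(9, 6))
  sm <- movingSmooth(x, window = 5)
  expect_equal(mean(sm), mean(x), tolerance = 1e-9)
  expect_true(all(sm >= min(x) - 1e-12 & sm <= max(x) + 1e-12))
  # interior linear stretch is a fixed point
  lin <- as.numeric(1:20)
  expect_equal(movingSmooth(lin, 5)[3:18], lin[3:18], tolerance = 1e-12)
  # median option
  expect_equal(movingSmooth(c(0, 0, 100, 0, 0), 3, "median"), rep(0, 5))
  # random series stay within bounds
  set.seed(9)
  for (i in 1:20) {
    v <- rnorm(50)
    s <- movingSmooth(v, 7)
    expect_true(all(s >= min(v) - 1e-12 & s <= max(v) + 1e-12))
  }
})

test_that("capacity classes follow the printed partition", {
  expect_equal(as.character(capacityClass(0)), "no")
  expect_equal(as.character(capacityClass(7)), "low")
  expect_equal(as.character(capacityClass(15)), "high")
  expect_equal(as.character(capacityClass(0:30)),
               c("no", rep("low", 10), rep("high", 20)))
  expect_error(capacityClass(-1), class = "beadphage_bad_capacity_input")
  expect_error(capacityClass(2.5), class = "beadphage_bad_capacity_input")
})

test_that("conservation holds end to end on a simulated closed field", {
  sc <- sceneConfig(nCells = 2, nBeads = 40, nFrames = 40,
                    fieldSize = c(192, 192),
                    schedule = data.frame(cell = c(1, 2), frame = c(8, 16),
                                          n_beads = c(3, 2)), seed = 7)
  sim <- simulateScene(sc)
  res <- suppressMessages(analyzeSequence(sim$sequence))
  df <- as.data.frame(res$series)
  truth <- trueCounts(sim$truth)
  # free + true ingested = initial free, exactly, before smoothing
  expect_true(all(df$free + truth$ingested == df$free[1]))
  expect_equal(df$ingested, truth$ingested)
  # monotone non-decreasing up to <= 1 bead of detection noise
  expect_true(all(diff(df$ingested) >= -1))
})
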