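test_that("collinear equally spaced points are a fixed point of smoothing", {
  raw <- cbind(2 * (0:30) + 5, -1.5 * (0:30) + 40)
  sm <- smoothPath(raw, window = 20)
  expect_lt(max(abs(sm - raw)), 1e-6)
})

test_that("smoothing reduces RMSE to the true line under Gaussian noise", {
  wins <- 0
  for (rep in 1:100) {
    set.seed(1000 + rep)
    n <- 60
    truth <- cbind(0.8 * (0:(n - 1)), 0.5 * (0:(n - 1)))
    raw <- truth + matrix(rnorm(2 * n, sd = 2), n, 2)
    sm <- smoothPath(raw, window = 20)
    rmse <- function(a) sqrt(mean((a - truth)^2))
    wins <- wins + (rmse(sm) < rmse(raw))
  }
  expect_equal(wins, 100)  # strictly better in every seeded replicate
})

test_that("short paths fall back to a global robust line fit", {
  raw <- rbind(c(0, 0), c(1.1, 2.0), c(2.0, 4.1))
  sm <- smoothPath(raw, window = 20)
  # the window covers the whole path, so one global line is evaluated at
  # every frame: the smoothed points must be exactly collinear in time
  expect_lt(max(abs(diff(diff(sm[, 1])))), 1e-8)
  expect_lt(max(abs(diff(diff(sm[, 2])))), 1e-8)
  expect_error(smoothPath(rbind(c(1, 1)), 20), class = "beadphage_short_path")
})

test_that("smoothing resists single-frame outliers (robust loss)", {
  raw <- cbind(as.numeric(0:29), rep(0, 30))
  raw[15, 2] <- 25  # one wild centroid
  sm <- smoothPath(raw, window = 20)
  expect_lt(abs(sm[15, 2]), 1.5)   # pulled back to the line
  lo <- 15 - 9; hi <- 15 + 10
  f <- lm(raw[lo:hi, 2] ~ I(lo:hi))
  ols15 <- unname(fitted(f))[15 - lo + 1]
  expect_lt(abs(sm[15, 2]), abs(ols15))  # beats plain least squares
})

test_that("smoothing is equivariant under translation and rotation", {
  set.seed(77)
  raw <- cbind(cumsum(rnorm(40)), cumsum(rnorm(40)))
  sm <- smoothPath(raw, window = 20)
  # translation
  sh <- smoothPath(raw + rep(c(13, -7), each = 40), window = 20)
  expect_lt(max(abs(sh - (sm + rep(c(13, -7), each = 40)))), 1e-6)
  # rotation
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sr <- smoothPath(raw %*% R, window = 20)
  expect_lt(max(abs(sr - sm %*% R)), 1e-6)
})

test_that("euclidean distance is the scaled start-to-end displacement", {
  expect_equal(euclideanDistance(rbind(c(4, 4)), 1.15), 0)
  expect_equal(euclideanDistance(rbind(c(0, 0), c(3, 4)), 1.15), 5.75)
  loop <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  expect_equal(euclideanDistance(loop, 1.15), 0)
  expect_error(euclideanDistance(matrix(numeric(), 0, 2)),
               class = "beadphage_short_path")
})

test_that("mean speed reproduces the constant-velocity worked value", {
  raw <- cbind(2 * (0:99), rep(0, 100))  # 2 px/frame
  v <- meanSpeed(raw, acquisitionMeta())  # 3.5 min/frame, 1.15 um/px
  expect_equal(v, 2 * 1.15 / 3.5, tolerance = 1e-12)
  expect_equal(round(v, 4), 0.6571)
  expect_equal(meanSpeed(cbind(c(5, 5), c(5, 5))), 0)
  expect_error(meanSpeed(rbind(c(1, 1))), class = "beadphage_short_path")
})

test_that("euclidean displacement never exceeds the cumulative path length", {
  set.seed(15)
  for (rep in 1:25) {
    raw <- cbind(cumsum(rnorm(30)), cumsum(rnorm(30)))
    expect_lte(euclideanDistance(raw, 1), pathLength(raw) + 1e-9)
    ps <- pathSet(raw)  # the PathSet validity also asserts this
    expect_s4_class(ps, "PathSet")
  }
})

test_that("zig-zag paths have smoothed speed below raw speed", {
  set.seed(99)
  for (rep in 1:20) {
    raw <- cbind(cumsum(rnorm(50)), cumsum(rnorm(50)))
    ps <- pathSet(raw)
    expect_lte(meanSpeed(ps@smoothed, frames = ps@frames),
               meanSpeed(ps@raw, frames = ps@frames))
  }
})

test_that("a ballistic path gives identical raw, smoothed and euclidean rates", {
  n <- 80
  raw <- cbind(1.7 * (0:(n - 1)) + 3, 0.9 * (0:(n - 1)) + 8)
  meta <- acquisitionMeta()
  ps <- pathSet(raw, meta)
  vr <- meanSpeed(ps@raw, meta); vs <- meanSpeed(ps@smoothed, meta)
  ve <- euclideanDistance(raw, pixelScale(meta)) / ((n - 1) * frameInterval(meta))
  expect_equal(vs / vr, 1, tolerance = 0.01)
  expect_equal(ve / vr, 1, tolerance = 0.01)
})

test_that("group summaries use the t quantile for the 95% interval", {
  s <- summarizeGroup(c(5, 5, 5))
  expect_equal(s$mean, 5); expect_equal(s$sd, 0)
  expect_equal(s$ci_hi - s$ci_lo, 0)
  s2 <- summarizeGroup(c(1, 2, 3))
  expect_equal(s2$mean, 2); expect_equal(s2$sd, 1)
  hw <- qt(0.975, 2) * 1 / sqrt(3)   # 4.302653 / sqrt(3) = 2.4841
  expect_equal(s2$ci_hi, 2 + hw, tolerance = 1e-9)
  expect_equal(round(hw, 4), 2.4841)
  expect_error(summarizeGroup(5), class = "beadphage_too_few_values")
})
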