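# Independent oracles and small fixture builders shared across tests.

# Closed-form pooled-variance two-sample t (independent of stats::t.test).
pooledTOracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Brute-force optimal one-to-one matching between two point sets of equal
# size by permutation enumeration (squared-distance cost). Returns the
# permutation (row -> column) with minimal total cost.
bruteForceMatch <- function(from, to) {
  n <- nrow(from)
  stopifnot(n == nrow(to), n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- NULL; bestCost <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum((from[, 1] - to[p, 1])^2 + (from[, 2] - to[p, 2])^2)
    if (cost < bestCost) { bestCost <- cost; best <- p }
  }
  list(perm = best, cost = bestCost)
}

# Render disks (value `tone`) onto a flat background matrix; centers are
# 0-based (x, y) as used by the detection module.
diskFrame <- function(dim, centers, radius, bg = 0.85, tone = 0.1) {
  m <- matrix(bg, dim[1], dim[2])
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    rows <- max(1, floor(cy + 1 - radius - 1)):min(dim[1], ceiling(cy + 1 + radius + 1))
    cols <- max(1, floor(cx + 1 - radius - 1)):min(dim[2], ceiling(cx + 1 + radius + 1))
    dy <- (rows - 1) - cy; dx <- (cols - 1) - cx
    m[rows, cols][outer(dy^2, dx^2, "+") <= radius^2] <- tone
  }
  m
}

# Detection table for synthetic per-frame positions: one detection per
# object per frame, for exercising the tracker without rendering.
detTable <- function(positions) {
  # positions: list by frame of n x 2 matrices
  do.call(rbind, lapply(seq_along(positions), function(f) {
    xy <- positions[[f]]
    if (is.null(xy) || nrow(xy) == 0) return(NULL)
    data.frame(frame = f - 1L, x = xy[, 1], y = xy[, 2])
  }))
}

# Small labelled detection table builder for ingestion-series tests.
seriesDets <- function(freeCounts) {
  do.call(rbind, lapply(seq_along(freeCounts), function(i) {
    k <- freeCounts[i]
    if (k == 0) return(NULL)
    data.frame(frame = i - 1L, label = "free", bead_count = rep(1L, k))
  }))
}
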