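#' Significance band for a p value
#'
#' p < 0.001 is "very_significant", p < 0.05 "significant", otherwise "ns".
#'
#' @param p p value(s) in [0,1]
#' @return character vector of bands
#' @export
significanceBand <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "very_significant", ifelse(p < 0.05, "significant", "ns"))
}

#' Unpaired two-tailed t test between two groups
#'
#' Student's pooled-variance two-sample t by default; the Welch variant is
#' available via `welch = TRUE` (the chosen variant is recorded in the
#' result). When both groups are constant with equal means the statistic is
#' undefined; p = 1 is returned by convention with a message.
#'
#' @param a,b numeric vectors, each of length >= 2, finite
#' @param welch use the Welch (unequal variance) variant
#' @return a [GroupComparison-class]
#' @export
unpairedTTest <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    .bp_stop("beadphage_too_few_values", "each group needs n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    .bp_stop("beadphage_nonfinite", "groups must be finite")
  res <- tryCatch(
    stats::t.test(a, b, var.equal = !welch),
    error = function(e) NULL)
  if (is.null(res)) {
    message("both groups constant with equal means; p = 1 by convention")
    t <- 0; df <- length(a) + length(b) - 2; p <- 1
  } else {
    t <- unname(res$statistic); df <- unname(res$parameter)
    p <- res$p.value
  }
  new("GroupComparison", groupA = as.numeric(a), groupB = as.numeric(b),
      tStatistic = t, df = df, pValue = p, band = significanceBand(p),
      method = if (welch) "welch" else "pooled")
}

#' Background-subtracted mean fluorescence intensity
#'
#' `markerPos * markerMean - isotypePos * isotypeMean`, the marker's
#' positive-gated fraction times the axis mean of its positive quadrants,
#' minus the same product for the isotype control. Fractions are carried
#' as proportions in [0, 1]; using percentages on both marker and isotype
#' only rescales the result by a constant. A negative MFI is reported
#' as-is with a warning.
#'
#' @param markerPos,isotypePos positive-gated proportions in [0, 1]
#' @param markerMean,isotypeMean axis means of the positive quadrants, >= 0
#' @return the MFI value
#' @export
mfi <- function(markerPos, markerMean, isotypePos, isotypeMean) {
  if (any(c(markerPos, isotypePos) < 0) || any(c(markerPos, isotypePos) > 1))
    .bp_stop("beadphage_bad_proportion",
             "positive-gated fractions must be proportions in [0, 1]")
  if (any(c(markerMean, isotypeMean) < 0))
    .bp_stop("beadphage_bad_mean", "axis means must be >= 0")
  out <- markerPos * markerMean - isotypePos * isotypeMean
  if (any(out < 0))
    warning("negative MFI after isotype subtraction (reported as-is)")
  out
}

#' Compare two analyzed groups and assemble a run report
#'
#' Takes the per-cell motion tables, ingestion series and capacity tables
#' of two groups (e.g. vehicle control and treated) and produces
#' deterministic summary tables: per-group mean/sd/95% CI for each motion
#' metric, pairwise unpaired t comparisons with significance bands, the
#' capacity-class distribution, and the normalized ingestion curves.
#'
#' @param groups named list with one entry per group; each entry a list
#'   with elements `motion` (from [motionTable()]), `series` (an
#'   [IngestionSeries-class]) and optionally `capacity` (from
#'   [capacityTable()])
#' @param welch use Welch t tests
#' @return list of data.frames: `summary`, `comparisons`, `capacity`,
#'   `curves`
#' @export
buildReport <- function(groups, welch = FALSE) {
  if (length(groups) < 1 || is.null(names(groups)) ||
      any(names(groups) == ""))
    .bp_stop("beadphage_missing_input", "groups must be a named list")
  for (g in names(groups)) {
    if (is.null(groups[[g]]$motion))
      .bp_stop("beadphage_missing_input",
               sprintf("group '%s' is missing the motion table", g))
    if (is.null(groups[[g]]$series))
      .bp_stop("beadphage_missing_input",
               sprintf("group '%s' is missing the ingestion series", g))
    if (nrow(groups[[g]]$motion) == 0)
      .bp_stop("beadphage_missing_input",
               sprintf("group '%s' has an empty motion table", g))
  }
  gnames <- sort(names(groups))
  metrics <- c("raw_speed", "smoothed_speed", "euclidean_um")

  summary <- do.call(rbind, lapply(gnames, function(g) {
    do.call(rbind, lapply(metrics, function(m) {
      s <- summarizeGroup(groups[[g]]$motion[[m]])
      data.frame(group = g, metric = m, n = s$n, mean = s$mean, sd = s$sd,
                 ci95_lo = s$ci_lo, ci95_hi = s$ci_hi)
    }))
  }))

  comparisons <- NULL
  if (length(gnames) >= 2) {
    pairs <- utils::combn(gnames, 2, simplify = FALSE)
    comparisons <- do.call(rbind, lapply(pairs, function(p) {
      do.call(rbind, lapply(metrics, function(m) {
        a <- groups[[p[1]]]$motion[[m]]; b <- groups[[p[2]]]$motion[[m]]
        cmp <- unpairedTTest(a, b, welch = welch)
        data.frame(metric = m, group_a = p[1], group_b = p[2],
                   n_a = length(a), n_b = length(b),
                   t = cmp@tStatistic, df = cmp@df, p = cmp@pValue,
                   band = cmp@band)
      }))
    }))
  }

  capacity <- do.call(rbind, lapply(gnames, function(g) {
    ct <- groups[[g]]$capacity
    if (is.null(ct) || nrow(ct) == 0) return(NULL)
    tab <- table(factor(ct$capacity_class, levels = c("no", "low", "high")))
    data.frame(group = g, class = names(tab), n = as.integer(tab),
               fraction = as.numeric(tab) / sum(tab))
  }))

  curves <- do.call(rbind, lapply(gnames, function(g) {
    df <- as.data.frame(groups[[g]]$series)
    cbind(group = g, df)
  }))

  list(summary = summary, comparisons = comparisons,
       capacity = capacity, curves = curves)
}
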