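#' @include select.R
NULL

#' Across-subject selection curve
#'
#' Per-step mean and standard deviation of the accuracy curves from several
#' subjects' selection traces, with an optional all-sensor baseline per
#' subject attached for reference lines.
#'
#' @param traces list of \code{\link{SelectionTrace}} objects with equal
#'   numbers of steps.
#' @param baselines optional numeric vector of per-subject all-sensor
#'   accuracies.
#' @return data.frame(step, mean, sd) with attribute \code{baselineMean}.
#' @export
selectionCurve <- function(traces, baselines = NULL) {
  ks <- vapply(traces, function(tr) length(tr@stepAccuracy), integer(1))
  if (length(unique(ks)) != 1) stop("traces have ragged lengths")
  M <- vapply(traces, function(tr) tr@stepAccuracy, numeric(ks[1]))
  M <- matrix(M, nrow = ks[1])
  out <- data.frame(step = seq_len(ks[1]),
                    mean = rowMeans(M),
                    sd = apply(M, 1, stats::sd))
  if (length(traces) == 1) out$sd <- 0
  attr(out, "baselineMean") <- if (is.null(baselines)) NA_real_
                               else mean(baselines)
  out
}

#' Axial sensor map of top-ranked sensors
#'
#' Projects the top-k selected sensors onto the axial (x-y) plane with their
#' selection rank, and optionally draws the map over the full montage.
#'
#' @param trace a \code{\link{SelectionTrace}}.
#' @param layout the matching \code{\link{SensorLayout}}.
#' @param topK ranks to include (default 9, the optimal-set size).
#' @param plot draw a base-graphics axial projection (default FALSE).
#' @return data.frame(rank, sensor_id, hemisphere, x, y, z).
#' @export
sensorMap <- function(trace, layout, topK = 9L, plot = FALSE) {
  if (topK > length(trace@rankedSensors))
    stop("topK exceeds the trace length")
  ids <- trace@rankedSensors[seq_len(topK)]
  ix <- match(ids, channelIds(layout))
  pos <- sensorPositions(layout)[ix, , drop = FALSE]
  out <- data.frame(rank = seq_len(topK), sensor_id = ids,
                    hemisphere = hemispheres(layout)[ix],
                    x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (plot) {
    all <- sensorPositions(layout)
    graphics::plot(all[, "x"], all[, "y"], pch = 1, col = "grey70",
                   asp = 1, xlab = "x (cm, left < 0)", ylab = "y (cm)",
                   main = sprintf("Top %d selected sensors", topK))
    cols <- grDevices::hcl.colors(topK, "viridis")
    graphics::points(out$x, out$y, pch = 19, col = cols, cex = 1.4)
    graphics::text(out$x, out$y, labels = out$rank, pos = 3, cex = 0.8)
  }
  out
}

#' Summarize decoding conditions across subjects
#'
#' Means and standard errors per condition (SE = sd / sqrt(n subjects)) and
#' paired t-tests (one- and two-tailed) for requested condition pairs.
#'
#' @param conditions named list; each element is either a numeric vector of
#'   per-subject accuracies or a list of \code{CVResult}s.
#' @param pairs optional list of 2-element character vectors naming
#'   conditions to compare (default: all pairs).
#' @return list(summary = data.frame(condition, mean, se, n), tests =
#'   data.frame(a, b, t, p_two, p_one, degenerate)).
#' @export
summarizeConditions <- function(conditions, pairs = NULL) {
  accs <- lapply(conditions, function(x) {
    if (is.numeric(x)) x
    else vapply(x, meanAccuracy, numeric(1))
  })
  ns <- lengths(accs)
  if (length(unique(ns)) != 1)
    stop("conditions cover different numbers of subjects")
  summary <- data.frame(
    condition = names(accs),
    mean = vapply(accs, mean, numeric(1)),
    se = vapply(accs, function(a) stats::sd(a) / sqrt(length(a)), numeric(1)),
    n = ns, row.names = NULL, stringsAsFactors = FALSE)
  if (is.null(pairs) && length(accs) > 1)
    pairs <- utils::combn(names(accs), 2, simplify = FALSE)
  tests <- NULL
  for (pr in pairs) {
    tt <- pairedTTest(accs[[pr[1]]], accs[[pr[2]]], tails = 2L)
    tests <- rbind(tests, data.frame(
      a = pr[1], b = pr[2], t = tt$t, p_two = tt$p,
      p_one = if (is.na(tt$p)) NA_real_ else tt$p / 2,
      degenerate = tt$degenerate, stringsAsFactors = FALSE))
  }
  list(summary = summary, tests = tests)
}
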