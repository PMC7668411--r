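#' @include decode.R
NULL

#' Step-wise greedy forward sensor selection
#'
#' Step 1 cross-validates every sensor alone (its 6 band features) and keeps
#' the best; step t appends each remaining sensor to the fixed optimal set
#' O1..O(t-1) and keeps the one giving the highest mean CV accuracy. Ties are
#' broken toward the lowest sensor index. The fold assignment is frozen once
#' and reused for every candidate at every step, so all comparisons are
#' paired. Step t performs exactly (nSensors - t + 1) CV evaluations.
#'
#' @param features a \code{\link{FeatureMatrix}}.
#' @param config a \code{\link{DecoderConfig}}; its seed freezes the folds.
#' @param KMax maximum number of sensors to select (default 50).
#' @param foldAssign optional explicit frozen fold assignment.
#' @return A \code{\link{SelectionTrace}} with per-step accuracies and the
#'   detected plateau step.
#' @export
forwardSelect <- function(features, config = decoderConfig(), KMax = 50L,
                          foldAssign = NULL) {
  KMax <- as.integer(KMax)
  if (KMax < 1L) stop("KMax must be >= 1")
  sensors <- features@sensorIds
  nS <- length(sensors)
  if (KMax > nS) stop("KMax cannot exceed the number of sensors")
  y <- droplevels(features@labels)
  if (is.null(foldAssign))
    foldAssign <- makeFolds(y, config@folds, config@seed)

  # Pre-scale the full matrix once per fold; per-column z-scoring commutes
  # with column subsetting, so candidate evaluation reduces to indexing.
  foldIds <- sort(unique(foldAssign))
  prep <- lapply(foldIds, function(f) {
    te <- foldAssign == f
    Xtr <- features@values[!te, , drop = FALSE]
    Xte <- features@values[te, , drop = FALSE]
    if (config@scaling == "zscore_trainfit") {
      sc <- .fit_scaler(Xtr)
      Xtr <- .apply_scaler(Xtr, sc)
      Xte <- .apply_scaler(Xte, sc)
    }
    list(Xtr = Xtr, Xte = Xte, ytr = y[!te], yte = y[te])
  })
  sensorCols <- lapply(seq_len(nS), function(s) (6L * (s - 1L) + 1L):(6L * s))

  evalSet <- function(cols) {
    mean(vapply(prep, function(p) {
      fit <- e1071::svm(p$Xtr[, cols, drop = FALSE], p$ytr,
                        kernel = "polynomial", degree = config@degree,
                        gamma = 1 / length(cols), coef0 = 0, cost = config@cost,
                        scale = FALSE)
      100 * mean(predict(fit, p$Xte[, cols, drop = FALSE]) == p$yte)
    }, numeric(1)))
  }

  selected <- integer(0)
  accs <- numeric(0)
  nEvals <- integer(0)
  for (step in seq_len(KMax)) {
    cands <- setdiff(seq_len(nS), selected)
    bestAcc <- -Inf
    bestCand <- NA_integer_
    for (cand in cands) {   # increasing index order => lowest-index tie-break
      a <- evalSet(unlist(sensorCols[c(selected, cand)]))
      if (a > bestAcc) {
        bestAcc <- a
        bestCand <- cand
      }
    }
    selected <- c(selected, bestCand)
    accs <- c(accs, bestAcc)
    nEvals <- c(nEvals, length(cands))
  }
  new("SelectionTrace", rankedSensors = sensors[selected],
      stepAccuracy = accs, KMax = KMax,
      plateauStep = findPlateau(accs), evalCounts = nEvals,
      sensorUniverse = sensors)
}

#' Detect the accuracy plateau of a selection trace
#'
#' Returns the first step t whose successor strictly decreases the accuracy
#' (accuracy[t+1] < accuracy[t]); NA if the curve never strictly decreases.
#' This matches judging convergence per run; for the across-subject reading,
#' pass the mean curve from \code{\link{selectionCurve}}.
#'
#' @param trace a \code{\link{SelectionTrace}} or a numeric accuracy vector.
#' @return Integer step index or NA.
#' @export
#' @examples
#' findPlateau(c(50, 60, 70, 69, 71))  # 3
findPlateau <- function(trace) {
  acc <- if (is(trace, "SelectionTrace")) trace@stepAccuracy else trace
  if (length(acc) == 0) stop("empty trace")
  drops <- which(diff(acc) < 0)
  if (length(drops) == 0) NA_integer_ else drops[1]
}

#' Tabular view of a selection trace
#'
#' @param trace a \code{\link{SelectionTrace}}.
#' @return data.frame(rank, sensor_id, accuracy) suitable for TSV export.
#' @export
traceTable <- function(trace) {
  stopifnot(is(trace, "SelectionTrace"))
  data.frame(rank = seq_along(trace@rankedSensors),
             sensor_id = trace@rankedSensors,
             accuracy = trace@stepAccuracy,
             stringsAsFactors = FALSE)
}

#' Cross-subject consensus (mode) analysis of selected sensors
#'
#' Counts, for every sensor, how many subjects include it in the top-k of
#' their selection trace — the spatial-consistency summary used to identify
#' sensors that recur across individuals.
#'
#' @param traces list of \code{\link{SelectionTrace}} objects, one per
#'   subject, all over the same sensor universe and with >= k ranks.
#' @param k top ranks to consider (default 50).
#' @return data.frame(sensor_id, count) sorted by descending count, ties by
#'   sensor id; attribute \code{k} records the cutoff.
#' @export
consensusTable <- function(traces, k = 50L) {
  if (length(traces) == 0) stop("no traces supplied")
  universes <- lapply(traces, function(tr) sort(tr@sensorUniverse))
  if (!all(vapply(universes, identical, logical(1), universes[[1]])))
    stop("traces have inconsistent sensor universes")
  short <- vapply(traces, function(tr) length(tr@rankedSensors) < k, logical(1))
  if (any(short)) stop("all traces must reach at least k ranks")
  tops <- lapply(traces, function(tr) tr@rankedSensors[seq_len(k)])
  counts <- table(unlist(tops))
  out <- data.frame(sensor_id = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sensor_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- as.integer(k)
  out
}
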