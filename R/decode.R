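#' @include features.R
NULL

#' Construct a DecoderConfig
#'
#' @param degree polynomial kernel order (default 2).
#' @param C box penalty (default 1).
#' @param folds number of CV folds (default 5).
#' @param seed fold-assignment seed (default 1).
#' @param scaling "zscore_trainfit" (default) or "none".
#' @return A validated \code{\link{DecoderConfig}}.
#' @export
decoderConfig <- function(degree = 2L, C = 1, folds = 5L, seed = 1L,
                          scaling = "zscore_trainfit") {
  new("DecoderConfig", degree = as.integer(degree), cost = C,
      folds = as.integer(folds), seed = as.integer(seed), scaling = scaling)
}

#' Stratified fold assignment
#'
#' Splits trials into \code{folds} folds with exactly count/folds trials of
#' every class per fold; deterministic for a given seed.
#'
#' @param labels factor (or coercible) of per-trial class labels.
#' @param folds number of folds.
#' @param seed RNG seed.
#' @return Integer vector of per-trial fold indices in 1..folds.
#' @export
#' @examples
#' table(makeFolds(rep(1:5, each = 60), 5, seed = 1), rep(1:5, each = 60))
makeFolds <- function(labels, folds = 5L, seed = 1L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts %% folds != 0))
    stop("every class count must be divisible by the number of folds")
  assign <- integer(length(labels))
  .with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      perm <- sample(idx)
      assign[perm] <- rep(seq_len(folds), each = length(idx) / folds)
    }
  })
  assign
}

## z-scoring parameters fit on training rows only; zero-variance columns are
## left centred but unscaled.
.fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < .Machine$double.eps] <- 1
  list(mu = mu, sd = sdv)
}
.apply_scaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

## Core CV loop over a plain matrix; reused by the selection fast path.
## Kernel: (gamma * <x, x'> + 0)^degree with gamma = 1/ncol after z-scoring.
.cv_accuracy <- function(X, y, foldAssign, config, confusion = FALSE) {
  folds <- sort(unique(foldAssign))
  acc <- numeric(length(folds))
  lev <- levels(y)
  conf <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(folds)) {
    te <- foldAssign == folds[i]
    ytr <- y[!te]
    if (nlevels(droplevels(ytr)) < 2)
      stop("degenerate training fold with fewer than 2 classes")
    Xtr <- X[!te, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    if (config@scaling == "zscore_trainfit") {
      sc <- .fit_scaler(Xtr)
      Xtr <- .apply_scaler(Xtr, sc)
      Xte <- .apply_scaler(Xte, sc)
    }
    fit <- e1071::svm(Xtr, ytr, kernel = "polynomial",
                      degree = config@degree, gamma = 1 / ncol(Xtr),
                      coef0 = 0, cost = config@cost, scale = FALSE)
    pred <- predict(fit, Xte)
    acc[i] <- 100 * mean(pred == y[te])
    if (confusion)
      conf[] <- conf + table(factor(y[te], lev), factor(pred, lev))
  }
  list(acc = acc, confusion = conf)
}

#' Cross-validated polynomial-kernel SVM decoding
#'
#' Stratified k-fold cross-validation of a 2nd-order polynomial SVM
#' (one-vs-one multiclass, C = 1). Per fold, feature columns are z-scored
#' with parameters fit on the training rows only; the kernel is
#' \eqn{(x \cdot x' / p)^2} with p the number of features, so results are
#' invariant to duplicating feature columns.
#'
#' @param features a \code{\link{FeatureMatrix}} with at least 2 classes and
#'   no non-finite values.
#' @param config a \code{\link{DecoderConfig}}.
#' @param foldAssign optional frozen per-trial fold assignment; computed from
#'   \code{config@seed} if omitted.
#' @return A \code{\link{CVResult}}.
#' @export
crossvalSvm <- function(features, config = decoderConfig(),
                        foldAssign = NULL) {
  X <- features@values
  y <- droplevels(features@labels)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (!all(is.finite(X))) stop("features contain non-finite values")
  if (is.null(foldAssign))
    foldAssign <- makeFolds(y, config@folds, config@seed)
  res <- .cv_accuracy(X, y, foldAssign, config, confusion = TRUE)
  new("CVResult", foldAccuracies = res$acc, meanAccuracy = mean(res$acc),
      sd = stats::sd(res$acc), confusion = res$confusion,
      foldAssignment = as.integer(foldAssign))
}

#' Decode using one hemisphere's sensors (or all)
#'
#' Subsets the feature matrix to the sensors whose layout tag matches
#' \code{side} and runs the cross-validated SVM. With 196 sensors, "all"
#' uses the full 1176 features and either hemisphere 588.
#'
#' @param features a \code{FeatureMatrix}.
#' @param layout a \code{\link{SensorLayout}} covering all feature sensors.
#' @param side "left", "right" or "all".
#' @param config a \code{DecoderConfig}.
#' @param foldAssign optional frozen fold assignment.
#' @return A \code{\link{CVResult}}.
#' @export
hemisphereEval <- function(features, layout, side = c("all", "left", "right"),
                           config = decoderConfig(), foldAssign = NULL) {
  side <- match.arg(side)
  missing <- setdiff(features@sensorIds, channelIds(layout))
  if (length(missing))
    stop("layout does not cover sensors: ", paste(missing, collapse = ", "))
  if (side == "all") {
    keep <- features@sensorIds
  } else {
    tags <- hemispheres(layout)[match(features@sensorIds, channelIds(layout))]
    keep <- features@sensorIds[tags == side]
  }
  if (length(keep) == 0) stop("no sensors on side '", side, "'")
  crossvalSvm(subsetFeatures(features, keep), config, foldAssign)
}

#' Paired t-test between per-subject accuracy vectors
#'
#' @param accA,accB numeric vectors of equal length >= 2 (e.g. per-subject
#'   accuracies under two conditions).
#' @param tails 1 or 2.
#' @return list(t, p, df, degenerate). When the paired differences have zero
#'   variance the statistic is undefined; identical vectors report t = 0,
#'   p = 1, and a constant non-zero shift reports NA with
#'   \code{degenerate = TRUE}.
#' @export
#' @examples
#' pairedTTest(c(1, 2, 3), c(2, 4, 6))
pairedTTest <- function(accA, accB, tails = 2L) {
  if (length(accA) != length(accB) || length(accA) < 2)
    stop("need equal-length vectors of length >= 2")
  d <- accA - accB
  if (stats::sd(d) < .Machine$double.eps) {
    if (abs(mean(d)) < .Machine$double.eps)
      return(list(t = 0, p = 1, df = length(d) - 1L, degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = NA_real_,
                df = length(d) - 1L, degenerate = TRUE))
  }
  tt <- stats::t.test(accA, accB, paired = TRUE)
  p <- tt$p.value
  if (tails == 1L) p <- p / 2
  list(t = unname(tt$statistic), p = p, df = unname(tt$parameter),
       degenerate = FALSE)
}
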