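#' @include AllGenerics.R
NULL

#' @describeIn nTrials trials in an EpochSet
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1])

#' @describeIn nTrials rows of a FeatureMatrix
#' @export
setMethod("nTrials", "FeatureMatrix", function(x) nrow(x@values))

#' @describeIn nChannels channels of an EpochSet
#' @export
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[2])

#' @describeIn nChannels sensors of a FeatureMatrix
#' @export
setMethod("nChannels", "FeatureMatrix", function(x) length(x@sensorIds))

#' @describeIn nChannels channels of a SensorLayout
#' @export
setMethod("nChannels", "SensorLayout", function(x) length(x@channelId))

#' @describeIn trialLabels labels of an EpochSet
#' @export
setMethod("trialLabels", "EpochSet", function(x) x@labels)

#' @describeIn trialLabels labels of a FeatureMatrix
#' @export
setMethod("trialLabels", "FeatureMatrix", function(x) x@labels)

#' @describeIn channelIds ids of an EpochSet
#' @export
setMethod("channelIds", "EpochSet", function(x) x@channelIds)

#' @describeIn channelIds sensors of a FeatureMatrix (column-block order)
#' @export
setMethod("channelIds", "FeatureMatrix", function(x) x@sensorIds)

#' @describeIn channelIds ids of a SensorLayout
#' @export
setMethod("channelIds", "SensorLayout", function(x) x@channelId)

#' @describeIn samplingRate rate of an EpochSet
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @describeIn timeAxis sample times of an EpochSet
#' @export
setMethod("timeAxis", "EpochSet", function(x)
  x@t0 + (seq_len(dim(x@data)[3]) - 1L) / x@fs)

#' @describeIn epochData array of an EpochSet
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' @describeIn featureValues matrix of a FeatureMatrix
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @describeIn hemispheres tags of a SensorLayout
#' @export
setMethod("hemispheres", "SensorLayout", function(x) x@hemisphere)

#' @describeIn sensorPositions positions of a SensorLayout
#' @export
setMethod("sensorPositions", "SensorLayout", function(x) {
  p <- x@position
  dimnames(p) <- list(x@channelId, c("x", "y", "z"))
  p
})

#' Column map of a FeatureMatrix
#'
#' @param x a FeatureMatrix.
#' @return data.frame(sensor, band, column) mapping each (sensor, band) pair
#'   to its column index.
#' @export
columnKey <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  x@columnKey
}

#' Per-fold and mean accuracies of a CVResult
#' @param x a CVResult.
#' @return Numeric vector of per-fold accuracies (percent).
#' @export
foldAccuracies <- function(x) { stopifnot(is(x, "CVResult")); x@foldAccuracies }

#' @rdname foldAccuracies
#' @return \code{meanAccuracy}: scalar mean accuracy (percent).
#' @export
meanAccuracy <- function(x) { stopifnot(is(x, "CVResult")); x@meanAccuracy }

#' Confusion matrix pooled over held-out folds
#' @param x a CVResult.
#' @return true class x predicted class count matrix.
#' @export
confusionMatrix <- function(x) { stopifnot(is(x, "CVResult")); x@confusion }

#' Fold assignment used by a CVResult
#' @param x a CVResult.
#' @return Integer per-trial fold index.
#' @export
foldAssignment <- function(x) { stopifnot(is(x, "CVResult")); x@foldAssignment }

#' Ranked sensors of a SelectionTrace
#' @param x a SelectionTrace.
#' @return Character vector of sensor ids in selection order.
#' @export
rankedSensors <- function(x) { stopifnot(is(x, "SelectionTrace")); x@rankedSensors }

#' Per-step accuracies of a SelectionTrace
#' @param x a SelectionTrace.
#' @return Numeric vector of mean CV accuracy (percent) per step.
#' @export
stepAccuracy <- function(x) { stopifnot(is(x, "SelectionTrace")); x@stepAccuracy }

#' Plateau step of a SelectionTrace
#' @param x a SelectionTrace.
#' @return Integer step index, or NA if no strict decrease was observed.
#' @export
plateauStep <- function(x) { stopifnot(is(x, "SelectionTrace")); x@plateauStep }

#' Candidate evaluations performed at each selection step
#' @param x a SelectionTrace.
#' @return Integer vector: CV evaluations per step.
#' @export
evalCounts <- function(x) { stopifnot(is(x, "SelectionTrace")); x@evalCounts }

#' Informative sensors / artifact trials of a GroundTruth
#' @param x a GroundTruth.
#' @return \code{informativeSensors}: per-class list of sensor indices.
#' @export
informativeSensors <- function(x) { stopifnot(is(x, "GroundTruth")); x@informativeSensors }

#' @rdname informativeSensors
#' @return \code{artifactTrials}: integer trial indices.
#' @export
artifactTrials <- function(x) { stopifnot(is(x, "GroundTruth")); x@artifactTrials }

#' @rdname informativeSensors
#' @return \code{flatChannels}: integer channel indices.
#' @export
flatChannels <- function(x) { stopifnot(is(x, "GroundTruth")); x@flatChannels }

#' Training history of a StackedAE
#' @param x a StackedAE.
#' @return List of per-stage data.frames with the loss (and its MSE/L2/KL
#'   components for pretraining stages) at each recorded epoch.
#' @export
trainingHistory <- function(x) { stopifnot(is(x, "StackedAE")); x@history }
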