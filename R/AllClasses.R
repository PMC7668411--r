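#' @import methods
NULL

#' Canonical frequency-band table
#'
#' The six oscillatory bands used throughout the package, in the fixed order
#' that defines feature-column layout: high-gamma, gamma, beta, alpha, theta,
#' delta. Each band is backed by one branch of the 7-level db4 wavelet
#' decomposition of a 1 kHz signal (details d3..d7 and approximation a7);
#' the nominal ranges are the conventional electrophysiological labels, the
#' operative edges are the dyadic ones (e.g. d3 spans 62.5-125 Hz).
#'
#' @return A data.frame with columns \code{band}, \code{coef} (wavelet
#'   branch), \code{low} and \code{high} (nominal range, Hz).
#' @export
#' @examples
#' bandTable()
bandTable <- function() {
  data.frame(
    band = c("highgamma", "gamma", "beta", "alpha", "theta", "delta"),
    coef = c("d3", "d4", "d5", "d6", "d7", "a7"),
    low  = c(61, 31, 16, 8, 4, 0.03),
    high = c(125, 59, 30, 16, 8, 4),
    stringsAsFactors = FALSE
  )
}

#' Band names in canonical column order
#' @return Character vector of the six band names.
#' @export
bandNames <- function() bandTable()$band

## ---------------------------------------------------------------------------
## SensorLayout
## ---------------------------------------------------------------------------

#' SensorLayout: 3-D gradiometer positions with hemisphere tags
#'
#' Container for a synthetic (or imported) sensor montage: Neuromag-style
#' channel names, positions on an upper head-shell in cm, and a left/right
#' hemisphere tag derived from the sign of the lateral (x) coordinate
#' (x < 0 is left).
#'
#' @slot channelId character, unique Neuromag-style names ("MEG0012", ...).
#' @slot position numeric matrix, n x 3 (x lateral, y anterior, z superior), cm.
#' @slot hemisphere character, "left" or "right" per channel.
#' @slot channelType character, currently always "gradiometer".
#' @export
setClass("SensorLayout",
  representation(
    channelId   = "character",
    position    = "matrix",
    hemisphere  = "character",
    channelType = "character"
  )
)

setValidity("SensorLayout", function(object) {
  n <- length(object@channelId)
  msg <- character()
  if (anyDuplicated(object@channelId)) msg <- c(msg, "channel ids must be unique")
  if (!is.numeric(object@position) || nrow(object@position) != n ||
      ncol(object@position) != 3)
    msg <- c(msg, "position must be an n x 3 numeric matrix")
  if (length(object@hemisphere) != n ||
      !all(object@hemisphere %in% c("left", "right")))
    msg <- c(msg, "hemisphere must be 'left'/'right' per channel")
  if (length(msg) == 0 &&
      !all(object@hemisphere == ifelse(object@position[, 1] < 0, "left", "right")))
    msg <- c(msg, "hemisphere tag inconsistent with sign of lateral coordinate")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SimulationConfig / GroundTruth
## ---------------------------------------------------------------------------

#' SimulationConfig: parameters of the synthetic epoch generator
#'
#' Defaults emulate the acquisition protocol the pipeline was designed for:
#' 196 gradiometers, 5 phrase classes, 60 trials per class, 4 kHz raw
#' sampling, epochs from -0.5 to 5 s around stimulus onset, and class-specific
#' band-limited oscillatory power planted on a known sensor subset during the
#' imagination (1-2 s) and production (2-3 s) windows.
#'
#' @slot nSensors integer, number of gradiometer channels.
#' @slot nClasses integer, number of phrase classes.
#' @slot nTrialsPerClass integer, trials per class.
#' @slot fsRaw numeric, raw sampling rate in Hz.
#' @slot epochWindow numeric length-2, epoch span in seconds relative to onset.
#' @slot plantedMap data.frame(class, sensor, band, amplitude): the planted
#'   ground-truth effects; amplitude is the burst standard deviation in the
#'   same units as \code{noiseSd}.
#' @slot noiseSd numeric, background noise standard deviation.
#' @slot amplitudeJitter numeric >= 0: sd of the per-trial lognormal
#'   multiplicative jitter on burst amplitudes (trial-to-trial band-power
#'   variability; 0 disables it).
#' @slot backgroundSpectrum character, "white" or "one_over_f".
#' @slot artifactRate numeric in [0,1], fraction of trials given artifacts.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(
    nSensors = "integer", nClasses = "integer", nTrialsPerClass = "integer",
    fsRaw = "numeric", epochWindow = "numeric", plantedMap = "data.frame",
    noiseSd = "numeric", amplitudeJitter = "numeric",
    backgroundSpectrum = "character",
    artifactRate = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pm <- object@plantedMap
  if (object@nSensors < 2L)
    msg <- c(msg, "nSensors must be >= 2")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@nTrialsPerClass < 1L) msg <- c(msg, "nTrialsPerClass must be >= 1")
  if (object@fsRaw <= 0) msg <- c(msg, "fsRaw must be positive")
  if (length(object@epochWindow) != 2 ||
      diff(object@epochWindow) <= 0)
    msg <- c(msg, "epochWindow must be an increasing length-2 vector")
  if (nrow(pm)) {
    if (!all(c("class", "sensor", "band", "amplitude") %in% names(pm)))
      msg <- c(msg, "plantedMap needs columns class, sensor, band, amplitude")
    else {
      if (any(pm$amplitude < 0)) msg <- c(msg, "effect amplitudes must be >= 0")
      if (any(pm$sensor < 1 | pm$sensor > object@nSensors))
        msg <- c(msg, "planted sensor indices must lie in 1..nSensors")
      if (!all(pm$band %in% bandNames()))
        msg <- c(msg, paste("planted band names must be one of:",
                            paste(bandNames(), collapse = ", ")))
      if (any(pm$class < 1 | pm$class > object@nClasses))
        msg <- c(msg, "planted classes must lie in 1..nClasses")
    }
  }
  if (object@amplitudeJitter < 0)
    msg <- c(msg, "amplitudeJitter must be >= 0")
  if (object@artifactRate < 0 || object@artifactRate > 1)
    msg <- c(msg, "artifactRate must be in [0,1]")
  if (!object@backgroundSpectrum %in% c("white", "one_over_f"))
    msg <- c(msg, "backgroundSpectrum must be 'white' or 'one_over_f'")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: planted structure of a synthetic dataset
#'
#' @slot informativeSensors list, per-class integer vectors of planted sensors.
#' @slot informativeBands list, per-class character vectors of planted bands.
#' @slot artifactTrials integer, indices of trials carrying injected artifacts.
#' @slot flatChannels integer, indices of channels zeroed flat.
#' @export
setClass("GroundTruth",
  representation(
    informativeSensors = "list", informativeBands = "list",
    artifactTrials = "integer", flatChannels = "integer"
  )
)

## ---------------------------------------------------------------------------
## EpochSet
## ---------------------------------------------------------------------------

#' EpochSet: multichannel epoched data
#'
#' Trials x channels x samples array of time-locked signal with per-trial
#' class labels, the sampling rate and the time of the first sample relative
#' to stimulus onset.
#'
#' @slot data numeric 3-D array, trials x channels x samples.
#' @slot fs numeric sampling rate, Hz.
#' @slot labels factor of length trials.
#' @slot channelIds character of length channels.
#' @slot t0 numeric, seconds of the first sample relative to stimulus onset.
#' @export
setClass("EpochSet",
  representation(
    data = "array", fs = "numeric", labels = "factor",
    channelIds = "character", t0 = "numeric"
  )
)

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3) msg <- c(msg, "data must be a 3-D array")
  else {
    if (length(object@labels) != d[1])
      msg <- c(msg, "labels length must equal number of trials")
    if (length(object@channelIds) != d[2])
      msg <- c(msg, "channelIds length must equal number of channels")
  }
  if (length(object@fs) != 1 || object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## RejectionReport
## ---------------------------------------------------------------------------

#' RejectionReport: what automated rejection removed and why
#'
#' @slot droppedChannels data.frame(channel_id, reason) with reason in
#'   \{flat, noisy\}.
#' @slot droppedTrials data.frame(trial, reason).
#' @slot retainedCounts table/integer vector of per-class retained trial counts.
#' @export
setClass("RejectionReport",
  representation(
    droppedChannels = "data.frame",
    droppedTrials = "data.frame",
    retainedCounts = "integer"
  )
)

## ---------------------------------------------------------------------------
## FeatureMatrix
## ---------------------------------------------------------------------------

#' FeatureMatrix: per-trial wavelet band-power features
#'
#' Trials x (sensors x 6 bands) matrix of RMS features with sensor-major,
#' band-minor column layout and an explicit (sensor, band) -> column map.
#'
#' @slot values numeric matrix, trials x (6 * n sensors), all values >= 0.
#' @slot sensorIds character, sensors in column-block order.
#' @slot labels factor, per-trial class labels.
#' @slot columnKey data.frame(sensor, band, column): total, invertible map.
#' @export
setClass("FeatureMatrix",
  representation(
    values = "matrix", sensorIds = "character",
    labels = "factor", columnKey = "data.frame"
  )
)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != 6L * length(object@sensorIds))
    msg <- c(msg, "column count must be 6 * number of sensors")
  if (length(object@labels) != nrow(object@values))
    msg <- c(msg, "labels length must equal number of trials")
  if (nrow(object@columnKey) != ncol(object@values) ||
      anyDuplicated(object@columnKey$column))
    msg <- c(msg, "columnKey must be a bijection onto columns")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DecoderConfig / CVResult
## ---------------------------------------------------------------------------

#' DecoderConfig: cross-validated SVM decoder settings
#'
#' Fixed to the decoding protocol used throughout: 2nd-order polynomial
#' kernel, box penalty C = 1, stratified 5-fold cross-validation, per-column
#' z-scoring fit on the training folds only.
#'
#' @slot degree integer polynomial order.
#' @slot cost numeric box penalty (the SVM C parameter; named cost to avoid
#'   colliding with \code{new()}'s Class argument).
#' @slot folds integer number of CV folds.
#' @slot seed integer seed for the stratified fold assignment.
#' @slot scaling character, "zscore_trainfit" or "none".
#' @export
setClass("DecoderConfig",
  representation(degree = "integer", cost = "numeric", folds = "integer",
                 seed = "integer", scaling = "character")
)

setValidity("DecoderConfig", function(object) {
  msg <- character()
  if (object@folds < 2L) msg <- c(msg, "folds must be >= 2")
  if (object@cost <= 0) msg <- c(msg, "C must be positive")
  if (!object@scaling %in% c("zscore_trainfit", "none"))
    msg <- c(msg, "scaling must be 'zscore_trainfit' or 'none'")
  if (length(msg)) msg else TRUE
})

#' CVResult: cross-validation outcome
#'
#' @slot foldAccuracies numeric, per-fold accuracy in percent.
#' @slot meanAccuracy numeric, mean of the fold accuracies (percent).
#' @slot sd numeric, standard deviation of fold accuracies (percent).
#' @slot confusion numeric matrix, true class x predicted class counts pooled
#'   over held-out folds.
#' @slot foldAssignment integer, per-trial fold index.
#' @export
setClass("CVResult",
  representation(foldAccuracies = "numeric", meanAccuracy = "numeric",
                 sd = "numeric", confusion = "matrix",
                 foldAssignment = "integer")
)

setValidity("CVResult", function(object) {
  msg <- character()
  if (abs(object@meanAccuracy - mean(object@foldAccuracies)) > 1e-8)
    msg <- c(msg, "meanAccuracy must equal the mean of foldAccuracies")
  if (any(object@foldAccuracies < 0 | object@foldAccuracies > 100))
    msg <- c(msg, "accuracies must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SelectionTrace
## ---------------------------------------------------------------------------

#' SelectionTrace: result of greedy forward sensor selection
#'
#' @slot rankedSensors character, selected sensors O1..OK in selection order.
#' @slot stepAccuracy numeric, mean CV accuracy (percent) after each step.
#' @slot KMax integer, requested maximum number of steps.
#' @slot plateauStep integer, first step after which accuracy strictly
#'   decreases (NA if the curve never decreases).
#' @slot evalCounts integer, number of candidate CV evaluations per step.
#' @slot sensorUniverse character, all sensor ids the selection ran over.
#' @export
setClass("SelectionTrace",
  representation(rankedSensors = "character", stepAccuracy = "numeric",
                 KMax = "integer", plateauStep = "integer",
                 evalCounts = "integer", sensorUniverse = "character")
)

setValidity("SelectionTrace", function(object) {
  msg <- character()
  if (anyDuplicated(object@rankedSensors))
    msg <- c(msg, "ranked sensors must be distinct")
  if (length(object@rankedSensors) > object@KMax)
    msg <- c(msg, "trace longer than KMax")
  if (length(object@stepAccuracy) != length(object@rankedSensors))
    msg <- c(msg, "stepAccuracy length must match rankedSensors")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## StackedAE
## ---------------------------------------------------------------------------

#' StackedAE: stacked sparse autoencoder
#'
#' Three greedily pretrained sigmoid autoencoder layers (default widths
#' 600/300/54 for 1176-dimensional input) stacked into an encoder, with the
#' per-layer decoders retained from pretraining and a softmax head used only
#' during supervised fine-tuning. Inputs are min-max scaled to [0,1] with a
#' transform fit on the training rows.
#'
#' @slot encoders list of layers, each list(W, b) mapping d_in -> d_hidden.
#' @slot decoders list of layers, each list(W, b) mapping d_hidden -> d_in.
#' @slot softmax list(W, b) classifier head fit during fine-tuning.
#' @slot scaler list(min, range) per-column min-max transform of the input.
#' @slot config list of hyperparameters used.
#' @slot history list of per-stage training-loss data.frames.
#' @export
setClass("StackedAE",
  representation(encoders = "list", decoders = "list", softmax = "list",
                 scaler = "list", config = "list", history = "list")
)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "SensorLayout", function(object) {
  tab <- table(object@hemisphere)
  cat("SensorLayout with", length(object@channelId), "channels (",
      paste(names(tab), tab, collapse = ", "), ")\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  cat(sprintf("  window: [%.3f, %.3f) s; classes: %s\n", object@t0,
              object@t0 + d[3] / object@fs,
              paste(levels(object@labels), collapse = ", ")))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d trials x %d features (%d sensors x 6 bands)\n",
              nrow(object@values), ncol(object@values),
              length(object@sensorIds)))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: mean accuracy %.2f%% (sd %.2f) over %d folds\n",
              object@meanAccuracy, object@sd, length(object@foldAccuracies)))
})

setMethod("show", "SelectionTrace", function(object) {
  k <- length(object@rankedSensors)
  cat(sprintf("SelectionTrace: %d ranked sensors (KMax %d)\n", k, object@KMax))
  if (k) cat(sprintf("  O1 = %s (%.2f%%); final accuracy %.2f%%; plateau step: %s\n",
                     object@rankedSensors[1], object@stepAccuracy[1],
                     object@stepAccuracy[k],
                     ifelse(is.na(object@plateauStep), "none",
                            object@plateauStep)))
})

setMethod("show", "StackedAE", function(object) {
  dims <- vapply(object@encoders, function(l) nrow(l$W), integer(1))
  cat("StackedAE:", paste(c(object@config$inputDim, dims), collapse = " -> "),
      "\n")
})
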