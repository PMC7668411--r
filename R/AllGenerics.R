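#' @include AllClasses.R
NULL

#' Number of trials
#' @param x an EpochSet or FeatureMatrix.
#' @return Integer trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Number of channels / sensors
#' @param x an EpochSet, FeatureMatrix or SensorLayout.
#' @return Integer channel count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Per-trial class labels
#' @param x an EpochSet or FeatureMatrix.
#' @return Factor of class labels.
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' Channel identifiers
#' @param x an EpochSet, FeatureMatrix or SensorLayout.
#' @return Character vector of channel ids.
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' Sampling rate in Hz
#' @param x an EpochSet.
#' @return Numeric sampling rate.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Time axis relative to stimulus onset
#' @param x an EpochSet.
#' @return Numeric vector of sample times in seconds.
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' Epoch data array
#' @param x an EpochSet.
#' @return The trials x channels x samples numeric array.
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' Feature value matrix
#' @param x a FeatureMatrix.
#' @return The trials x features numeric matrix.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Sensor hemisphere tags
#' @param x a SensorLayout.
#' @return Character vector, "left"/"right" per channel.
#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))

#' Sensor positions
#' @param x a SensorLayout.
#' @return n x 3 numeric matrix of positions in cm.
#' @export
setGeneric("sensorPositions", function(x) standardGeneric("sensorPositions"))
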