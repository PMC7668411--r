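#' @include db4.R
NULL

.make_column_key <- function(sensorIds) {
  data.frame(
    sensor = rep(sensorIds, each = 6L),
    band = rep(bandNames(), times = length(sensorIds)),
    column = seq_len(6L * length(sensorIds)),
    stringsAsFactors = FALSE
  )
}

#' Extract wavelet band-power RMS features
#'
#' For every trial and channel the windowed signal is decomposed with the
#' 7-level db4 wavelet, the six band reconstructions (d3..d7, a7) are formed,
#' and the RMS of each is taken. Columns are laid out sensor-major,
#' band-minor: for 196 sensors this yields the canonical 1176-dimensional
#' feature vector per trial.
#'
#' @param epochs an \code{EpochSet} restricted to a single analysis window
#'   (nominally 1 s at 1 kHz).
#' @return A \code{\link{FeatureMatrix}}.
#' @export
extractFeatures <- function(epochs) {
  d <- dim(epochs@data)
  if (d[3] < 2^7)
    stop("window too short for the 7-level wavelet decomposition")
  nCh <- d[2]
  # one vectorized transform over all trial x channel signals at once
  X <- matrix(aperm(epochs@data, c(3, 1, 2)), nrow = d[3])  # cols: (trial, ch)
  rms <- .wavelet_rms_mat(X)                                # 6 x (trials*ch)
  vals <- matrix(0, d[1], 6L * nCh)
  for (ch in seq_len(nCh))
    vals[, (6L * (ch - 1L) + 1L):(6L * ch)] <-
      t(rms[, (d[1] * (ch - 1L) + 1L):(d[1] * ch), drop = FALSE])
  key <- .make_column_key(epochs@channelIds)
  colnames(vals) <- paste(key$sensor, key$band, sep = "_")
  new("FeatureMatrix", values = vals, sensorIds = epochs@channelIds,
      labels = epochs@labels, columnKey = key)
}

#' Subset a FeatureMatrix to selected sensors
#'
#' Keeps exactly the six band columns of each requested sensor, in the
#' requested sensor order, and rebuilds the column map.
#'
#' @param features a \code{FeatureMatrix}.
#' @param sensors character vector of sensor ids (must be known).
#' @return The reduced \code{FeatureMatrix}.
#' @export
subsetFeatures <- function(features, sensors) {
  unknown <- setdiff(sensors, features@sensorIds)
  if (length(unknown))
    stop("unknown sensor id(s): ", paste(unknown, collapse = ", "))
  cols <- unlist(lapply(sensors, function(s)
    features@columnKey$column[features@columnKey$sensor == s]))
  key <- .make_column_key(sensors)
  vals <- features@values[, cols, drop = FALSE]
  colnames(vals) <- paste(key$sensor, key$band, sep = "_")
  new("FeatureMatrix", values = vals, sensorIds = as.character(sensors),
      labels = features@labels, columnKey = key)
}
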