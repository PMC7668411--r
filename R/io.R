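#' @include report.R
NULL

#' Write / read a sensor layout as CSV
#'
#' Columns: channel_id, x, y, z, hemisphere.
#'
#' @param layout a \code{\link{SensorLayout}}.
#' @param path CSV file path.
#' @return \code{writeLayoutCsv}: the path, invisibly. \code{readLayoutCsv}:
#'   a \code{SensorLayout}.
#' @export
writeLayoutCsv <- function(layout, path) {
  pos <- sensorPositions(layout)
  utils::write.csv(data.frame(channel_id = channelIds(layout),
                              x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
                              hemisphere = hemispheres(layout)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLayoutCsv
#' @export
readLayoutCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("SensorLayout", channelId = df$channel_id,
      position = cbind(x = df$x, y = df$y, z = df$z),
      hemisphere = df$hemisphere,
      channelType = rep("gradiometer", nrow(df)))
}

#' Write / read an EpochSet as a plain-text container
#'
#' A directory holding \code{meta.json} (fs, t0, labels, channel ids,
#' dimensions) and \code{data.csv} with one row per (trial, channel) pair.
#'
#' @param epochs an \code{EpochSet}.
#' @param dir directory to create/fill.
#' @return \code{writeEpochsDir}: the directory, invisibly;
#'   \code{readEpochsDir}: an \code{EpochSet}.
#' @export
writeEpochsDir <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs@data)
  meta <- list(fs = epochs@fs, t0 = epochs@t0,
               labels = as.character(epochs@labels),
               channel_ids = epochs@channelIds, dim = d)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  flat <- matrix(aperm(epochs@data, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  utils::write.table(flat, file.path(dir, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname writeEpochsDir
#' @export
readEpochsDir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "data.csv"), sep = ","))
  d <- as.integer(meta$dim)
  dat <- aperm(array(t(flat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  new("EpochSet", data = dat, fs = meta$fs,
      labels = factor(meta$labels), channelIds = meta$channel_ids,
      t0 = meta$t0)
}

#' Write / read a FeatureMatrix as TSV
#'
#' Header columns are \code{label} then \code{sensorid_band} per feature.
#'
#' @param features a \code{\link{FeatureMatrix}}.
#' @param path TSV file path.
#' @return \code{writeFeaturesTsv}: the path, invisibly;
#'   \code{readFeaturesTsv}: a \code{FeatureMatrix}.
#' @export
writeFeaturesTsv <- function(features, path) {
  df <- data.frame(label = as.character(features@labels),
                   features@values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeaturesTsv
#' @export
readFeaturesTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  sensors <- unique(sub("_[a-z]+$", "", colnames(vals)))
  key <- .make_column_key(sensors)
  new("FeatureMatrix", values = vals, sensorIds = sensors,
      labels = factor(df$label), columnKey = key)
}

#' Serialize a SelectionTrace or CVResult to JSON
#'
#' @param x a \code{SelectionTrace} or \code{CVResult}.
#' @param path JSON file path.
#' @return The path, invisibly.
#' @export
writeResultJson <- function(x, path) {
  obj <- if (is(x, "SelectionTrace")) {
    list(type = "SelectionTrace", ranked_sensors = x@rankedSensors,
         step_accuracy = x@stepAccuracy, k_max = x@KMax,
         plateau_step = if (is.na(x@plateauStep)) NULL else x@plateauStep,
         eval_counts = x@evalCounts, sensor_universe = x@sensorUniverse)
  } else if (is(x, "CVResult")) {
    list(type = "CVResult", fold_accuracies = x@foldAccuracies,
         mean_accuracy = x@meanAccuracy, sd = x@sd,
         confusion = x@confusion, fold_assignment = x@foldAssignment)
  } else stop("unsupported object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a SelectionTrace back from JSON
#'
#' @param path JSON file written by \code{\link{writeResultJson}}.
#' @return A \code{SelectionTrace}.
#' @export
readTraceJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "SelectionTrace")) stop("not a SelectionTrace file")
  new("SelectionTrace", rankedSensors = obj$ranked_sensors,
      stepAccuracy = obj$step_accuracy, KMax = as.integer(obj$k_max),
      plateauStep = if (is.null(obj$plateau_step)) NA_integer_
                    else as.integer(obj$plateau_step),
      evalCounts = as.integer(obj$eval_counts),
      sensorUniverse = obj$sensor_universe)
}
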