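#' @include AllClasses.R
NULL

## Column-wise IIR filtering of a samples x signals matrix: the numerator is
## a convolution pass and the denominator a recursive pass, both handled at
## C level by stats::filter, so a whole epoch set filters in one call.
.iir_mat <- function(X, b, a) {
  b <- b / a[1]
  a <- a / a[1]
  m <- ncol(X)
  fir <- stats::filter(rbind(matrix(0, length(b) - 1L, m), X), b,
                       method = "convolution", sides = 1)
  fir <- fir[-seq_len(length(b) - 1L), , drop = FALSE]
  y <- if (length(a) > 1L) stats::filter(fir, -a[-1L], method = "recursive")
       else fir
  matrix(y, nrow(X), m)
}

## Zero-phase (forward-backward) filtering with odd-reflection edge padding,
## so constants and slow trends pass the filter without edge transients.
.filtfilt_mat <- function(filt, X) {
  n <- nrow(X)
  p <- min(n - 1L, 300L)
  Xe <- rbind(2 * matrix(X[1L, ], p, ncol(X), byrow = TRUE) -
                X[(p + 1L):2L, , drop = FALSE],
              X,
              2 * matrix(X[n, ], p, ncol(X), byrow = TRUE) -
                X[(n - 1L):(n - p), , drop = FALSE])
  b <- as.numeric(filt$b)
  a <- as.numeric(filt$a)
  Y <- .iir_mat(Xe, b, a)
  Y <- .iir_mat(Y[nrow(Y):1L, , drop = FALSE], b, a)
  Y[nrow(Y):1L, , drop = FALSE][(p + 1L):(p + n), , drop = FALSE]
}

## Apply a zero-phase filter to every trial x channel.
.filt_all <- function(epochs, filt) {
  d <- dim(epochs@data)
  X <- matrix(aperm(epochs@data, c(3, 1, 2)), nrow = d[3])
  Y <- .filtfilt_mat(filt, X)
  epochs@data <- aperm(array(Y, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  epochs
}

#' Low-pass filter an EpochSet
#'
#' Zero-phase 4th-order Butterworth low-pass (applied forward and backward,
#' so the effective attenuation is doubled and no group delay distorts the
#' time-locked windows).
#'
#' @param epochs an \code{EpochSet}.
#' @param cutoff cutoff frequency in Hz (default 250).
#' @param order filter order (default 4).
#' @return The filtered \code{EpochSet}; sampling rate unchanged.
#' @export
lowpassEpochs <- function(epochs, cutoff = 250, order = 4L) {
  if (cutoff >= epochs@fs / 2)
    stop("cutoff must be below the Nyquist frequency")
  .filt_all(epochs, signal::butter(order, cutoff / (epochs@fs / 2), "low"))
}

#' Notch line noise and harmonics
#'
#' Narrow zero-phase band-stop filters at the line frequency and its
#' harmonics up to \code{nHarmonics * base} (harmonics at or above Nyquist
#' are skipped). Notch width is \code{f0 / Q}.
#'
#' @param epochs an \code{EpochSet}.
#' @param base line frequency in Hz (default 60).
#' @param nHarmonics number of harmonics including the base (default 4, i.e.
#'   60/120/180/240 Hz).
#' @param Q notch quality factor (default 30).
#' @return The filtered \code{EpochSet}.
#' @export
notchEpochs <- function(epochs, base = 60, nHarmonics = 4L, Q = 30) {
  nyq <- epochs@fs / 2
  for (h in seq_len(nHarmonics)) {
    f0 <- h * base
    if (f0 >= nyq) break
    bw <- f0 / Q
    w <- c(max(f0 - bw / 2, 0.01), min(f0 + bw / 2, nyq * 0.999)) / nyq
    epochs <- .filt_all(epochs, signal::butter(2, w, "stop"))
  }
  epochs
}

#' Resample an EpochSet to a lower rate
#'
#' Downsamples to \code{round(samples * targetFs / fs)} samples per epoch.
#' For integer decimation factors this is direct decimation (anti-aliasing
#' is provided by the low-pass already applied in the conditioning chain);
#' otherwise polyphase resampling is used.
#'
#' @param epochs an \code{EpochSet}.
#' @param targetFs target sampling rate, Hz (default 1000); must not exceed
#'   the current rate.
#' @return The resampled \code{EpochSet} with \code{fs} updated.
#' @export
resampleEpochs <- function(epochs, targetFs = 1000) {
  fs <- epochs@fs
  if (targetFs > fs) stop("upsampling is not supported")
  if (targetFs == fs) return(epochs)
  d <- dim(epochs@data)
  nOut <- round(d[3] * targetFs / fs)
  ratio <- fs / targetFs
  newDat <- array(0, dim = c(d[1], d[2], nOut))
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- 1L + round(ratio) * (seq_len(nOut) - 1L)
    newDat <- epochs@data[, , idx, drop = FALSE]
  } else {
    for (tr in seq_len(d[1]))
      for (ch in seq_len(d[2])) {
        y <- signal::resample(epochs@data[tr, ch, ], p = targetFs, q = fs)
        newDat[tr, ch, ] <- y[seq_len(nOut)]
      }
  }
  new("EpochSet", data = newDat, fs = targetFs, labels = epochs@labels,
      channelIds = epochs@channelIds, t0 = epochs@t0)
}

#' Reject flat or overly noisy channels
#'
#' A channel is flat if its pooled standard deviation is below
#' \code{flatEps}, and noisy if the z-score of its log-variance across the
#' remaining channels exceeds \code{noisyZ}.
#'
#' @param epochs an \code{EpochSet} with at least 2 channels.
#' @param flatEps absolute sd threshold for flatness (default 1e-10).
#' @param noisyZ log-variance z-score threshold (default 5).
#' @return list(epochs, report) where report is a
#'   \code{\link{RejectionReport}}.
#' @export
rejectChannels <- function(epochs, flatEps = 1e-10, noisyZ = 5) {
  d <- dim(epochs@data)
  if (d[2] < 2) stop("need at least 2 channels")
  sds <- apply(epochs@data, 2, stats::sd)
  flat <- sds < flatEps
  logv <- log(sds[!flat]^2)
  z <- (logv - mean(logv)) / max(stats::sd(logv), .Machine$double.eps)
  noisy <- logical(d[2])
  noisy[!flat] <- z > noisyZ
  drop <- flat | noisy
  if (all(drop)) stop("all channels rejected")
  dropped <- data.frame(
    channel_id = epochs@channelIds[drop],
    reason = ifelse(flat[drop], "flat", "noisy"),
    stringsAsFactors = FALSE)
  kept <- new("EpochSet", data = epochs@data[, !drop, , drop = FALSE],
              fs = epochs@fs, labels = epochs@labels,
              channelIds = epochs@channelIds[!drop], t0 = epochs@t0)
  report <- new("RejectionReport", droppedChannels = dropped,
                droppedTrials = data.frame(trial = integer(),
                                           reason = character()),
                retainedCounts = c(table(epochs@labels)))
  list(epochs = kept, report = report)
}

#' Reject trials by absolute peak amplitude
#'
#' Automated surrogate for visual artifact inspection: any trial whose
#' absolute peak exceeds \code{peakThresh} on any channel is removed. With
#' \code{peakThresh = NULL} the threshold is set to three times the median
#' per-trial peak, which cleanly separates blink-scale transients (an order
#' of magnitude above background) from clean trials.
#'
#' @param epochs an \code{EpochSet}.
#' @param peakThresh positive amplitude threshold, or NULL for the automatic
#'   rule.
#' @return list(epochs, report).
#' @export
rejectTrials <- function(epochs, peakThresh = NULL) {
  d <- dim(epochs@data)
  peaks <- apply(abs(epochs@data), 1, max)
  if (is.null(peakThresh)) peakThresh <- 3 * stats::median(peaks)
  if (peakThresh <= 0) stop("peakThresh must be positive")
  bad <- peaks > peakThresh
  keptLabels <- epochs@labels[!bad]
  if (length(keptLabels) == 0 || any(table(keptLabels) == 0))
    stop("trial rejection emptied at least one class")
  kept <- new("EpochSet", data = epochs@data[!bad, , , drop = FALSE],
              fs = epochs@fs, labels = keptLabels,
              channelIds = epochs@channelIds, t0 = epochs@t0)
  report <- new("RejectionReport",
                droppedChannels = data.frame(channel_id = character(),
                                             reason = character()),
                droppedTrials = data.frame(trial = which(bad),
                                           reason = rep("peak", sum(bad))),
                retainedCounts = c(table(kept@labels)))
  list(epochs = kept, report = report)
}

#' Balance trial counts across classes
#'
#' Keeps the first \code{nPerClass} trials per class in original acquisition
#' order, so every class contributes equally to decoding.
#'
#' @param epochs an \code{EpochSet}.
#' @param nPerClass trials to retain per class (default 60).
#' @return The balanced \code{EpochSet}.
#' @export
balanceTrials <- function(epochs, nPerClass = 60L) {
  counts <- table(epochs@labels)
  short <- counts < nPerClass
  if (any(short))
    stop("class ", paste(names(counts)[short], collapse = ", "),
         " has fewer than ", nPerClass, " trials")
  keep <- unlist(lapply(levels(epochs@labels), function(cl)
    which(epochs@labels == cl)[seq_len(nPerClass)]))
  keep <- sort(keep)
  new("EpochSet", data = epochs@data[keep, , , drop = FALSE], fs = epochs@fs,
      labels = epochs@labels[keep], channelIds = epochs@channelIds,
      t0 = epochs@t0)
}

#' Extract the imagination or production analysis window
#'
#' Imagination covers [1, 2) s after stimulus onset (the fixation-cross delay
#' period); production covers [2, 3) s (the first second after the
#' articulation cue). At 1 kHz each window is exactly 1000 samples.
#'
#' @param epochs an \code{EpochSet}.
#' @param stage "imagination" or "production".
#' @param window optional explicit c(start, end) in seconds overriding the
#'   stage defaults.
#' @return An \code{EpochSet} restricted to the window (\code{t0} updated).
#' @export
extractWindow <- function(epochs, stage = c("imagination", "production"),
                          window = NULL) {
  if (is.null(window)) {
    stage <- match.arg(stage)
    window <- if (stage == "imagination") c(1, 2) else c(2, 3)
  }
  t <- timeAxis(epochs)
  idx <- which(t >= window[1] & t < window[2])
  if (length(idx) == 0 || window[1] < t[1] - 1e-9 ||
      window[2] > t[length(t)] + 1 / epochs@fs + 1e-9)
    stop("requested window lies outside the epoch span")
  new("EpochSet", data = epochs@data[, , idx, drop = FALSE], fs = epochs@fs,
      labels = epochs@labels, channelIds = epochs@channelIds,
      t0 = t[idx[1]])
}

#' Full signal-conditioning chain
#'
#' Fixed-order pipeline: low-pass, notch, resample, channel rejection, trial
#' rejection, trial balancing, window extraction.
#'
#' @param epochs raw \code{EpochSet}.
#' @param stage analysis window, "imagination" or "production".
#' @param cutoff low-pass cutoff, Hz.
#' @param notchBase line frequency, Hz.
#' @param targetFs resampling target, Hz.
#' @param nPerClass trials kept per class.
#' @param flatEps,noisyZ,peakThresh rejection thresholds (see
#'   \code{\link{rejectChannels}}, \code{\link{rejectTrials}}).
#' @return list(epochs, channelReport, trialReport).
#' @export
preprocessChain <- function(epochs, stage = "production", cutoff = 250,
                            notchBase = 60, targetFs = 1000, nPerClass = 60L,
                            flatEps = 1e-10, noisyZ = 5, peakThresh = NULL) {
  epochs <- lowpassEpochs(epochs, cutoff)
  epochs <- notchEpochs(epochs, notchBase)
  epochs <- resampleEpochs(epochs, targetFs)
  cr <- rejectChannels(epochs, flatEps, noisyZ)
  tr <- rejectTrials(cr$epochs, peakThresh)
  epochs <- balanceTrials(tr$epochs, nPerClass)
  epochs <- extractWindow(epochs, stage)
  list(epochs = epochs, channelReport = cr$report, trialReport = tr$report)
}
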