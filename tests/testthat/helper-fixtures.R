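# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small planted dataset exercised by several modules: 8 sensors, 4 of them
# informative with strong effects, 10 trials/class at 1 kHz.
smallSim <- function() fixture("smallSim", function() {
  cfg <- simConfig(nSensors = 8L, nTrialsPerClass = 10L, fsRaw = 1000,
                   epochWindow = c(0, 3.2),
                   plantedMap = defaultPlantedMap(8L, nInformative = 4L,
                                                  amplitude = 3),
                   seed = 7L)
  sim <- simulateEpochs(cfg)
  sim$config <- cfg
  sim
})

# Background-only dataset (no planted effects): clean baseline for the
# artifact-injection and rejection-threshold checks.
cleanSim <- function() fixture("cleanSim", function() {
  cfg <- simConfig(nSensors = 6L, nTrialsPerClass = 10L, fsRaw = 1000,
                   epochWindow = c(0, 3.2), plantedMap = data.frame(),
                   seed = 8L)
  sim <- simulateEpochs(cfg)
  sim$config <- cfg
  sim
})

smallFeatures <- function() fixture("smallFeatures", function() {
  sim <- smallSim()
  extractFeatures(extractWindow(sim$epochs, "production"))
})

# Build a FeatureMatrix directly from Gaussian clusters: cheap decode/select
# fixture with per-sensor-block class structure.
syntheticFeatureMatrix <- function(nSensors, nPerClass, nClasses = 5L,
                                   informative = seq_len(nSensors),
                                   effect = 1, seed = 1L, sd = 1) {
  set.seed(seed)
  n <- nClasses * nPerClass
  labels <- factor(rep(seq_len(nClasses), each = nPerClass))
  p <- 6L * nSensors
  X <- abs(matrix(rnorm(n * p, mean = 3, sd = sd), n, p))
  for (s in informative) {
    cols <- (6L * (s - 1L) + 1L):(6L * s)
    shift <- matrix(rnorm(nClasses * 6L, sd = effect), nClasses, 6L)
    X[, cols] <- abs(X[, cols] + shift[as.integer(labels), ])
  }
  ids <- sprintf("MEG%04d", 10L * seq_len(nSensors) + 2L)
  key <- do.call(rbind, lapply(ids, function(id)
    data.frame(sensor = id, band = bandNames(), stringsAsFactors = FALSE)))
  key$column <- seq_len(p)
  colnames(X) <- paste(key$sensor, key$band, sep = "_")
  new("FeatureMatrix", values = X, sensorIds = ids, labels = labels,
      columnKey = key)
}

# Plain EpochSet around a given data array (defaults keep validity happy).
epochsFromArray <- function(dat, fs = 1000, t0 = 0, labels = NULL,
                            ids = NULL) {
  d <- dim(dat)
  if (is.null(labels)) labels <- factor(rep_len(1:2, d[1]))
  if (is.null(ids)) ids <- sprintf("MEG%04d", 10L * seq_len(d[2]) + 2L)
  new("EpochSet", data = dat, fs = fs, labels = labels, channelIds = ids,
      t0 = t0)
}

# FFT band power of a signal between lo and hi Hz (periodogram integral);
# independent oracle for the wavelet band placement checks.
fftBandPower <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- abs(fft(x))^2 / n
  f <- (seq_len(n) - 1L) * fs / n
  half <- f <= fs / 2
  sum(P[half & f >= lo & f <= hi])
}

# Dyadic band edges actually realized by the 7-level transform at 1 kHz.
dyadicBandEdges <- function() {
  lev <- c(3, 4, 5, 6, 7)
  data.frame(band = bandNames(),
             lo = c(1000 / 2^(lev + 1), 0),
             hi = c(1000 / 2^lev, 1000 / 2^8))
}
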