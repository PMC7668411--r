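test_that("rms follows the closed form", {
  expect_equal(rmsValue(c(3, 4)), sqrt((9 + 16) / 2))
  expect_equal(rmsValue(rep(-2.5, 10)), 2.5)
  x <- rnorm(100)
  expect_equal(rmsValue(-3 * x), 3 * rmsValue(x))
  expect_error(rmsValue(numeric(0)), "empty")
})

test_that("wavelet branches sum back to the input (perfect reconstruction)", {
  set.seed(11)
  for (n in c(128L, 1000L, 1234L)) {
    x <- rnorm(n)
    dec <- db4Decompose(x, 7L)
    expect_equal(db4Reconstruct(dec), x, tolerance = 1e-10)
    total <- rowSums(waveletBands(x))
    for (l in 1:2) {   # add back the discarded d1, d2 branches
      d <- dec
      d$details <- lapply(dec$details, function(v) numeric(length(v)))
      d$details[[l]] <- dec$details[[l]]
      d$approx <- numeric(length(dec$approx))
      total <- total + db4Reconstruct(d)
    }
    expect_lt(max(abs(total - x)) / max(abs(x)), 1e-8)
  }
  expect_error(db4Decompose(rnorm(100), 7L), "too short")
})

test_that("DC lives in the approximation branch only", {
  b <- waveletBands(rep(3, 512))
  expect_equal(b[, "delta"], rep(3, 512), tolerance = 1e-8)
  for (band in setdiff(bandNames(), "delta"))
    expect_lt(max(abs(b[, band])), 1e-8)
})

test_that("band energy lands where the FFT oracle says it should", {
  # a 40 Hz tone is gamma (d4: 31.25-62.5 Hz at 1 kHz)
  x <- sin(2 * pi * 40 * (0:999) / 1000)
  b <- waveletBands(x)
  energies <- colSums(b^2)
  expect_equal(names(which.max(energies)), "gamma")

  # random in-band tone mixtures, all six bands
  edges <- dyadicBandEdges()
  set.seed(21)
  for (rep in 1:20) {
    i <- sample(nrow(edges), 1)
    lo <- max(edges$lo[i], 0.5)
    f <- runif(3, lo + 0.15 * (edges$hi[i] - lo),
               edges$hi[i] - 0.15 * (edges$hi[i] - lo))
    x <- rowSums(sapply(f, function(ff)
      sin(2 * pi * ff * (0:999) / 1000 + runif(1, 0, 2 * pi))))
    rmsb <- sqrt(colMeans(waveletBands(x)^2))
    expect_equal(names(which.max(rmsb)), edges$band[i])
  }
})

test_that("feature matrices have the sensor-major 6-band column layout", {
  set.seed(3)
  ep <- epochsFromArray(array(rnorm(6 * 196 * 256), dim = c(6, 196, 256)),
                        labels = factor(rep(1:2, 3)))
  fm <- extractFeatures(ep)
  expect_equal(ncol(featureValues(fm)), 1176L)  # 196 sensors x 6 bands
  expect_true(all(featureValues(fm) >= 0))
  expect_true(all(is.finite(featureValues(fm))))
  key <- columnKey(fm)
  expect_equal(nrow(key), 1176L)
  expect_equal(key$band[1:6], bandNames())
  expect_equal(unique(key$sensor[1:6]), channelIds(ep)[1])

  half <- subsetFeatures(fm, channelIds(ep)[1:98])
  expect_equal(ncol(featureValues(half)), 588L)
  nine <- subsetFeatures(fm, channelIds(ep)[5:13])
  expect_equal(ncol(featureValues(nine)), 54L)
  one <- subsetFeatures(fm, channelIds(ep)[7])
  expect_equal(ncol(featureValues(one)), 6L)

  # subsetting to everything is the identity
  all <- subsetFeatures(fm, channelIds(ep))
  expect_equal(featureValues(all), featureValues(fm))
  expect_error(subsetFeatures(fm, "MEG9999"), "unknown")

  # subset columns equal the matching full-matrix columns
  cols <- key$column[key$sensor == channelIds(ep)[7]]
  expect_equal(unname(featureValues(one)),
               unname(featureValues(fm)[, cols, drop = FALSE]))
})

test_that("a planted effect dominates its own feature column", {
  pm <- data.frame(class = 2L, sensor = 4L, band = "alpha", amplitude = 5)
  cfg <- simConfig(nSensors = 6L, nTrialsPerClass = 8L, fsRaw = 1000,
                   epochWindow = c(1.9, 3.1), plantedMap = pm, seed = 13L)
  sim <- simulateEpochs(cfg)
  fm <- extractFeatures(extractWindow(sim$epochs, "production"))
  X <- featureValues(fm)
  y <- trialLabels(fm)
  spread <- apply(X, 2, function(col) {
    m <- tapply(col, y, mean)
    max(m) - min(m)
  })
  key <- columnKey(fm)
  target <- key$column[key$sensor == channelIds(fm)[4] & key$band == "alpha"]
  expect_equal(unname(which.max(spread)), target)
})

test_that("feature extraction is equivariant to trial permutation", {
  sim <- smallSim()
  ep <- extractWindow(sim$epochs, "imagination")
  perm <- rev(seq_len(nTrials(ep)))
  epPerm <- new("EpochSet", data = epochData(ep)[perm, , , drop = FALSE],
                fs = samplingRate(ep), labels = trialLabels(ep)[perm],
                channelIds = channelIds(ep), t0 = ep@t0)
  f1 <- extractFeatures(ep)
  f2 <- extractFeatures(epPerm)
  expect_equal(featureValues(f2), featureValues(f1)[perm, ],
               ignore_attr = TRUE)
})
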