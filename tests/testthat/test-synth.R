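test_that("layout splits sensors evenly across hemispheres on a 10 cm shell", {
  lay <- makeLayout(196L, seed = 1L)
  expect_equal(unname(table(hemispheres(lay))["left"]), 98L,
               ignore_attr = TRUE)
  expect_equal(unname(table(hemispheres(lay))["right"]), 98L,
               ignore_attr = TRUE)
  pos <- sensorPositions(lay)
  expect_true(all(abs(sqrt(rowSums(pos^2)) - 10) < 1e-6))
  expect_true(all(pos[, "z"] > 0))
  expect_identical(hemispheres(lay),
                   unname(ifelse(pos[, "x"] < 0, "left", "right")))
  expect_false(anyDuplicated(channelIds(lay)) > 0)

  tiny <- makeLayout(2L, seed = 0L)
  expect_setequal(hemispheres(tiny), c("left", "right"))

  expect_error(makeLayout(7L), "even")
  expect_error(makeLayout(0L), "even")
})

test_that("layout generation is deterministic given the seed", {
  a <- makeLayout(48L, seed = 3L)
  b <- makeLayout(48L, seed = 3L)
  expect_identical(sensorPositions(a), sensorPositions(b))
  c <- makeLayout(48L, seed = 4L)
  expect_false(identical(sensorPositions(a), sensorPositions(c)))
})

test_that("simulated epochs are balanced, sized and bit-reproducible", {
  cfg <- simConfig(nSensors = 4L, nTrialsPerClass = 60L, fsRaw = 250,
                   epochWindow = c(0, 1),
                   plantedMap = defaultPlantedMap(4L, nInformative = 2L))
  sim <- simulateEpochs(cfg)
  expect_equal(nTrials(sim$epochs), 300L)      # 60 trials x 5 phrases
  expect_true(all(table(trialLabels(sim$epochs)) == 60L))
  sim2 <- simulateEpochs(cfg)
  expect_identical(epochData(sim$epochs), epochData(sim2$epochs))

  bad <- cfg
  bad@plantedMap$band[1] <- "mu"
  expect_error(simulateEpochs(bad), "band")
})

test_that("planted band effects land in the stated band and window", {
  # single planted effect: class 1, sensor 2, alpha, in both task windows
  pm <- data.frame(class = 1L, sensor = 2L, band = "alpha", amplitude = 5)
  cfg <- simConfig(nSensors = 4L, nTrialsPerClass = 6L, fsRaw = 500,
                   epochWindow = c(0, 3), plantedMap = pm,
                   amplitudeJitter = 0, seed = 3L)
  sim <- simulateEpochs(cfg)
  ep <- sim$epochs
  t <- timeAxis(ep)
  idx <- which(t >= 1 & t < 2)
  cls1 <- which(trialLabels(ep) == "1")
  bt <- bandTable()
  pow <- sapply(seq_len(nrow(bt)), function(i) {
    mean(sapply(cls1, function(tr)
      fftBandPower(epochData(ep)[tr, 2, idx], 500, bt$low[i], bt$high[i])))
  })
  expect_equal(bt$band[which.max(pow)], "alpha")
  # control window (before the task) carries no alpha excess on that sensor
  pre <- which(t < 1)
  alphaTask <- mean(sapply(cls1, function(tr)
    fftBandPower(epochData(ep)[tr, 2, idx], 500, 8, 16)))
  alphaPre <- mean(sapply(cls1, function(tr)
    fftBandPower(epochData(ep)[tr, 2, pre], 500, 8, 16)))
  expect_gt(alphaTask, 5 * alphaPre)
})

test_that("a strongly planted sensor wins the single-sensor decoding scan", {
  pm <- data.frame(class = 2L, sensor = 3L, band = "alpha", amplitude = 6)
  cfg <- simConfig(nSensors = 6L, nTrialsPerClass = 10L, fsRaw = 1000,
                   epochWindow = c(1.9, 3.1), plantedMap = pm, seed = 5L)
  sim <- simulateEpochs(cfg)
  fm <- extractFeatures(extractWindow(sim$epochs, "production"))
  dc <- decoderConfig(seed = 2L)
  fa <- makeFolds(trialLabels(fm), 5L, 2L)
  accs <- vapply(channelIds(fm), function(id)
    meanAccuracy(crossvalSvm(subsetFeatures(fm, id), dc, fa)), numeric(1))
  expect_equal(unname(which.max(accs)), 3L)
})

test_that("artifact injection flags exactly the corrupted trials", {
  sim <- smallSim()
  # rate 0 leaves the data untouched
  out0 <- injectArtifacts(sim$epochs, rate = 0, seed = 9L)
  expect_identical(epochData(out0$epochs), epochData(sim$epochs))
  expect_length(artifactTrials(out0$truth), 0L)

  out <- injectArtifacts(sim$epochs, rate = 0.2, seed = 9L,
                         flatChannel = 5L)
  expect_length(artifactTrials(out$truth), round(0.2 * nTrials(sim$epochs)))
  expect_identical(flatChannels(out$truth), 5L)
  expect_equal(stats::sd(epochData(out$epochs)[, 5, ]), 0)
  # corrupted trials carry a large added transient on a frontal channel
  tr <- artifactTrials(out$truth)[1]
  x <- epochData(out$epochs)[tr, 1, ]
  x0 <- epochData(sim$epochs)[tr, 1, ]
  expect_gt(max(abs(x - x0)), 5 * stats::sd(epochData(sim$epochs)))
  expect_error(injectArtifacts(sim$epochs, rate = 1.2), "rate")
})
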