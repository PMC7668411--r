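test_that("low-pass filter preserves DC and kills far-stopband tones", {
  n <- 4000
  dc <- epochsFromArray(array(2, dim = c(1, 1, n)), fs = 4000)
  out <- lowpassEpochs(dc, 250)
  expect_equal(epochData(out)[1, 1, ], epochData(dc)[1, 1, ],
               tolerance = 1e-6)
  expect_equal(samplingRate(out), samplingRate(dc))

  t <- (0:(n - 1)) / 4000
  tone <- epochsFromArray(array(sin(2 * pi * 400 * t), dim = c(1, 1, n)),
                          fs = 4000)
  out <- lowpassEpochs(tone, 250)
  expect_lt(rmsValue(epochData(out)[1, 1, ]),
            0.05 * rmsValue(epochData(tone)[1, 1, ]))

  expect_error(lowpassEpochs(dc, 2000), "Nyquist")
})

test_that("notch removes line frequency but spares nearby physiology", {
  n <- 4000
  t <- (0:(n - 1)) / 1000
  line <- epochsFromArray(array(sin(2 * pi * 60 * t), dim = c(1, 1, n)))
  out <- notchEpochs(line, 60)
  core <- 500:3500  # ignore filter edge transients
  expect_lt(rmsValue(epochData(out)[1, 1, core]),
            0.05 * rmsValue(epochData(line)[1, 1, core]))

  slow <- epochsFromArray(array(sin(2 * pi * 10 * t), dim = c(1, 1, n)))
  out <- notchEpochs(slow, 60)
  expect_gt(rmsValue(epochData(out)[1, 1, core]),
            0.98 * rmsValue(epochData(slow)[1, 1, core]))

  zero <- epochsFromArray(array(0, dim = c(1, 1, n)))
  expect_equal(epochData(notchEpochs(zero, 60))[1, 1, ], rep(0, n))
})

test_that("resampling respects the length arithmetic and spectral content", {
  z <- epochsFromArray(array(0, dim = c(1, 1, 22000)), fs = 4000)
  out <- resampleEpochs(z, 1000)
  expect_equal(dim(epochData(out))[3], 5500L)
  expect_equal(samplingRate(out), 1000)

  t <- (0:3999) / 2000
  tone <- epochsFromArray(array(sin(2 * pi * 40 * t), dim = c(1, 1, 4000)),
                          fs = 2000)
  out <- resampleEpochs(tone, 1000)
  x <- epochData(out)[1, 1, ]
  P <- abs(fft(x))^2
  f <- (seq_along(x) - 1) * 1000 / length(x)
  expect_equal(f[which.max(P[f <= 500])], 40, tolerance = 1)

  expect_identical(resampleEpochs(tone, 2000), tone)
  expect_error(resampleEpochs(tone, 4000), "upsampl")
})

test_that("channel rejection catches flat and pathological channels only", {
  sim <- smallSim()
  art <- injectArtifacts(sim$epochs, rate = 0, seed = 1L, flatChannel = 3L)
  res <- rejectChannels(art$epochs)
  expect_equal(res$report@droppedChannels$channel_id,
               channelIds(sim$epochs)[3])
  expect_equal(res$report@droppedChannels$reason, "flat")
  expect_equal(nChannels(res$epochs), 7L)

  clean <- rejectChannels(sim$epochs)
  expect_equal(nrow(clean$report@droppedChannels), 0L)
  expect_equal(nChannels(clean$epochs), 8L)

  flat2 <- epochsFromArray(array(0, dim = c(2, 2, 200)))
  expect_error(rejectChannels(flat2), "all channels")
})

test_that("trial rejection removes exactly the artifact-bearing trials", {
  sim <- cleanSim()
  art <- injectArtifacts(sim$epochs, rate = 0.1, seed = 4L)
  res <- rejectTrials(art$epochs)
  expect_setequal(res$report@droppedTrials$trial,
                  artifactTrials(art$truth))
  expect_equal(sum(res$report@retainedCounts), nTrials(res$epochs))

  none <- rejectTrials(sim$epochs, peakThresh = Inf)
  expect_equal(nTrials(none$epochs), nTrials(sim$epochs))
})

test_that("trial balancing keeps the first n per class in acquisition order", {
  sim <- smallSim()
  bal <- balanceTrials(sim$epochs, 10L)          # already balanced: identity
  expect_identical(epochData(bal), epochData(sim$epochs))

  # drop two trials of class 4 and ask for 10 -> failure naming the class
  drop <- which(trialLabels(sim$epochs) == "4")[9:10]
  keep <- setdiff(seq_len(nTrials(sim$epochs)), drop)
  sub <- new("EpochSet", data = epochData(sim$epochs)[keep, , , drop = FALSE],
             fs = samplingRate(sim$epochs),
             labels = trialLabels(sim$epochs)[keep],
             channelIds = channelIds(sim$epochs), t0 = sim$epochs@t0)
  expect_error(balanceTrials(sub, 10L), "class 4")

  bal8 <- balanceTrials(sim$epochs, 8L)          # keeps the FIRST 8 per class
  expect_true(all(table(trialLabels(bal8)) == 8L))
  first8 <- unlist(lapply(levels(trialLabels(sim$epochs)), function(cl)
    which(trialLabels(sim$epochs) == cl)[1:8]))
  expect_identical(epochData(bal8),
                   epochData(sim$epochs)[sort(first8), , , drop = FALSE])
})

test_that("analysis windows are disjoint 1 s segments locked to the cue", {
  sim <- smallSim()
  im <- extractWindow(sim$epochs, "imagination")
  pr <- extractWindow(sim$epochs, "production")
  expect_equal(dim(epochData(im))[3], 1000L)
  expect_equal(dim(epochData(pr))[3], 1000L)
  expect_lt(max(timeAxis(im)), min(timeAxis(pr)) + 1e-12)
  expect_equal(im@t0, 1)
  expect_equal(pr@t0, 2)
  expect_error(extractWindow(sim$epochs, window = c(5, 6)), "outside")
})

test_that("the full conditioning chain yields exact per-class counts", {
  sim <- cleanSim()
  art <- injectArtifacts(sim$epochs, rate = 0.1, seed = 2L)
  out <- preprocessChain(art$epochs, stage = "production", nPerClass = 8L)
  expect_true(all(table(trialLabels(out$epochs)) == 8L))
  expect_false(anyNA(epochData(out$epochs)))
  expect_equal(samplingRate(out$epochs), 1000)
  expect_equal(dim(epochData(out$epochs))[3], 1000L)
})
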