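test_that("stratified folds split 60 trials/class into 12 + 48", {
  y <- rep(1:5, each = 60)
  fa <- makeFolds(y, 5L, seed = 1L)
  tab <- table(fa, y)
  expect_true(all(tab == 12L))                  # 12 per phrase per fold
  expect_true(all(colSums(tab[-1, ]) == 48L))   # 48 per phrase for training
  fa2 <- makeFolds(y, 5L, seed = 2L)
  expect_false(identical(fa, fa2))
  expect_true(all(table(fa2, y) == 12L))
  expect_error(makeFolds(rep(1:5, each = 7), 5L), "divisible")
})

test_that("well-separated clusters decode perfectly and chance data do not", {
  fm <- syntheticFeatureMatrix(2L, nPerClass = 10L, effect = 30, sd = 0.2,
                               seed = 5L)
  cv <- crossvalSvm(fm, decoderConfig(seed = 1L))
  expect_equal(meanAccuracy(cv), 100)
  expect_equal(meanAccuracy(cv), mean(foldAccuracies(cv)))
  # confusion-matrix trace / total equals the mean accuracy
  expect_equal(100 * sum(diag(confusionMatrix(cv))) /
                 sum(confusionMatrix(cv)), meanAccuracy(cv))
  expect_equal(unname(rowSums(confusionMatrix(cv))), rep(10, 5))
})

test_that("duplicating every feature column leaves the decoder unchanged", {
  fm <- syntheticFeatureMatrix(3L, nPerClass = 10L, effect = 1.2, seed = 9L)
  fa <- makeFolds(trialLabels(fm), 5L, 3L)
  dc <- decoderConfig(seed = 3L)
  base <- crossvalSvm(fm, dc, fa)
  dup <- new("FeatureMatrix",
             values = cbind(featureValues(fm), featureValues(fm)),
             sensorIds = c(channelIds(fm), paste0(channelIds(fm), "b")),
             labels = trialLabels(fm),
             columnKey = data.frame(
               sensor = rep(c(channelIds(fm), paste0(channelIds(fm), "b")),
                            each = 6),
               band = rep(bandNames(), 6),
               column = 1:36))
  expect_equal(meanAccuracy(crossvalSvm(dup, dc, fa)), meanAccuracy(base))
})

test_that("decoding is invariant to consistent trial reordering", {
  fm <- syntheticFeatureMatrix(3L, nPerClass = 10L, effect = 1, seed = 2L)
  fa <- makeFolds(trialLabels(fm), 5L, 7L)
  dc <- decoderConfig(seed = 7L)
  base <- crossvalSvm(fm, dc, fa)
  perm <- sample(nTrials(fm))
  fmP <- new("FeatureMatrix", values = featureValues(fm)[perm, ],
             sensorIds = channelIds(fm), labels = trialLabels(fm)[perm],
             columnKey = columnKey(fm))
  permuted <- crossvalSvm(fmP, dc, fa[perm])
  expect_equal(meanAccuracy(permuted), meanAccuracy(base), tolerance = 1e-9)
})

test_that("hemisphere evaluation partitions the sensor set", {
  lay <- makeLayout(8L, seed = 1L)
  sim <- smallSim()
  fm <- smallFeatures()
  # smallSim channel ids match makeLayout(8) ids by construction
  expect_setequal(channelIds(fm), channelIds(lay))
  left <- channelIds(lay)[hemispheres(lay) == "left"]
  right <- channelIds(lay)[hemispheres(lay) == "right"]
  expect_length(intersect(left, right), 0L)
  expect_setequal(c(left, right), channelIds(fm))

  fa <- makeFolds(trialLabels(fm), 5L, 1L)
  dc <- decoderConfig(seed = 1L)
  cvL <- hemisphereEval(fm, lay, "left", dc, fa)
  cvAll <- hemisphereEval(fm, lay, "all", dc, fa)
  expect_s4_class(cvL, "CVResult")
  expect_equal(meanAccuracy(cvAll),
               meanAccuracy(crossvalSvm(fm, dc, fa)))
})

test_that("paired t-test matches the textbook computation", {
  res <- pairedTTest(c(1, 2, 3), c(2, 4, 6), tails = 2L)
  expect_equal(res$t, -3.4641016, tolerance = 1e-6)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_false(res$degenerate)

  one <- pairedTTest(c(1, 2, 3), c(2, 4, 6), tails = 1L)
  expect_equal(one$p, res$p / 2)

  same <- pairedTTest(c(50, 60, 70), c(50, 60, 70))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  shift <- pairedTTest(c(50, 60, 70), c(40, 50, 60))
  expect_true(shift$degenerate)
  expect_true(is.na(shift$p))

  expect_error(pairedTTest(1:3, 1:4), "equal-length")
})
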