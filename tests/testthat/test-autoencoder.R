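test_that("KL sparsity penalty is non-negative and zero only at the target", {
  expect_equal(klSparsity(rep(0.15, 10), 0.15), 0)
  expect_gt(klSparsity(c(0.15, 0.4), 0.15), 0)
  expect_gt(klSparsity(rep(0.9, 5), 0.1), klSparsity(rep(0.3, 5), 0.1))
  set.seed(1)
  for (i in 1:20) expect_gte(klSparsity(runif(8, 0.01, 0.99), 0.2), 0)
})

test_that("a repeated input vector is reconstructed essentially perfectly", {
  v <- runif(20)
  X <- matrix(rep(v, each = 30), 30, 20)
  fit <- pretrainLayer(X, 5L, l2 = 0, beta = 0.1, rho = 0.2,
                       maxEpochs = 300L, seed = 2L)
  expect_lt(tail(fit$history$mse, 1) / ncol(X), 1e-4)
  A1 <- 1 / (1 + exp(-sweep(X %*% t(fit$encoder$W), 2, fit$encoder$b, "+")))
  expect_true(all(A1 < 1))
})

test_that("the loss decomposes exactly into MSE + L2 + KL terms", {
  set.seed(4)
  X <- matrix(runif(40 * 12), 40, 12)
  fit <- pretrainLayer(X, 6L, l2 = 0.01, beta = 2, rho = 0.2,
                       maxEpochs = 60L, chunk = 20L, seed = 3L)
  h <- fit$history
  expect_equal(h$loss, h$mse + h$l2 + h$kl)
  expect_true(all(h$kl >= 0))
  # switching a coefficient off removes its term exactly
  noKl <- pretrainLayer(X, 6L, l2 = 0.01, beta = 0, rho = 0.2,
                        maxEpochs = 40L, seed = 3L)
  expect_true(all(noKl$history$kl == 0))
  noL2 <- pretrainLayer(X, 6L, l2 = 0, beta = 2, rho = 0.2,
                        maxEpochs = 40L, seed = 3L)
  expect_true(all(noL2$history$l2 == 0))
})

test_that("plain-autoencoder ablation matches an independent MSE trainer", {
  set.seed(6)
  X <- matrix(runif(50 * 10), 50, 10)
  fit <- pretrainLayer(X, 4L, l2 = 0, beta = 0, rho = 0.2,
                       maxEpochs = 200L, seed = 5L)
  expect_equal(fit$history$loss, fit$history$mse)  # pure reconstruction loss

  # independent trainer: same architecture, numeric-free-gradient optim
  sig <- function(z) 1 / (1 + exp(-z))
  n <- nrow(X); dIn <- ncol(X); dH <- 4L
  sizes <- c(dH * dIn, dH, dIn * dH, dIn)
  fn <- function(par) {
    s <- cumsum(sizes)
    W1 <- matrix(par[1:s[1]], dH, dIn); b1 <- par[(s[1] + 1):s[2]]
    W2 <- matrix(par[(s[2] + 1):s[3]], dIn, dH); b2 <- par[(s[3] + 1):s[4]]
    A2 <- sig(sweep(sig(sweep(X %*% t(W1), 2, b1, "+")) %*% t(W2), 2, b2, "+"))
    sum((A2 - X)^2) / n
  }
  set.seed(5)
  r <- sqrt(6 / (dIn + dH))
  par0 <- c(runif(dH * dIn, -r, r), numeric(dH),
            runif(dIn * dH, -r, r), numeric(dIn))
  ref <- optim(par0, fn, method = "BFGS", control = list(maxit = 300))
  # both trainers reach losses of the same order, far below the start
  expect_lt(tail(fit$history$loss, 1), 0.5 * fit$history$loss[1])
  expect_lt(tail(fit$history$loss, 1), 2 * ref$value + 0.05)
})

test_that("training histories are finite and non-increasing", {
  set.seed(8)
  X <- matrix(runif(30 * 8), 30, 8)
  fit <- pretrainLayer(X, 4L, maxEpochs = 100L, chunk = 10L, seed = 1L)
  h <- fit$history$loss
  expect_true(all(is.finite(h)))
  expect_true(all(diff(h) <= 1e-6))
  stack <- buildStack(X, factor(rep(1:2, 15)),
                      aeConfig(layerDims = c(6L, 5L, 4L), maxEpochs = 50L,
                               fineTuneEpochs = 40L, chunk = 10L), seed = 2L)
  for (h2 in trainingHistory(stack))
    expect_true(all(diff(h2$loss) <= 1e-6))
})

test_that("the stack respects the layer dimension contract", {
  set.seed(9)
  X <- matrix(runif(60 * 24), 60, 24)
  y <- factor(rep(1:5, 12))
  cfg <- aeConfig(layerDims = c(18L, 12L, 6L), maxEpochs = 60L,
                  fineTuneEpochs = 40L)
  stack <- buildStack(X, y, cfg, seed = 1L)
  dims <- vapply(stack@encoders, function(l) nrow(l$W), integer(1))
  expect_equal(dims, c(18L, 12L, 6L))
  expect_equal(vapply(stack@encoders, function(l) ncol(l$W), integer(1)),
               c(24L, 18L, 12L))
  expect_equal(vapply(stack@decoders, function(l) nrow(l$W), integer(1)),
               c(24L, 18L, 12L))

  codes <- encodeFeatures(stack, X)
  Z <- featureValues(codes)
  expect_equal(ncol(Z), 6L)
  expect_true(all(Z > 0 & Z < 1))

  # row-wise independence: permuting rows permutes codes identically
  perm <- sample(nrow(X))
  Zp <- featureValues(encodeFeatures(stack, X[perm, ]))
  expect_equal(Zp, Z[perm, ], ignore_attr = TRUE)

  expect_error(encodeFeatures(stack, X[, 1:10]), "does not match")

  stack2 <- buildStack(X, y, cfg, seed = 99L)
  expect_false(identical(stack@encoders[[1]]$W, stack2@encoders[[1]]$W))
  expect_error(aeConfig(layerDims = c(10L, 10L)), "decreasing")
})

test_that("per-fold AE refits keep 48/12 splits and produce valid codes", {
  fm <- syntheticFeatureMatrix(4L, nPerClass = 10L, effect = 2, seed = 31L)
  cfg <- aeConfig(layerDims = c(18L, 12L, 6L), maxEpochs = 60L,
                  fineTuneEpochs = 40L)
  dc <- decoderConfig(seed = 2L)
  res <- aePipelineEval(fm, cfg, dc, seed = 4L)
  expect_s4_class(res, "CVResult")
  expect_length(foldAccuracies(res), 5L)
  fa <- foldAssignment(res)
  expect_true(all(table(fa, trialLabels(fm)) == 2L))  # 10/class over 5 folds
  single <- aePipelineEval(fm, cfg, dc, seed = 4L, singleSplit = TRUE)
  expect_length(foldAccuracies(single), 1L)
})
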