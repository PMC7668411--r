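#' @include decode.R
NULL

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' KL-divergence sparsity penalty
#'
#' Sum over hidden units of KL(rho || rhoHat_j) for Bernoulli means: the
#' penalty is zero iff every mean activation equals the target proportion
#' rho, and grows without bound as activations saturate.
#'
#' @param rhoHat numeric vector of mean hidden activations, each in (0,1).
#' @param rho target sparsity proportion.
#' @return Non-negative scalar.
#' @export
klSparsity <- function(rhoHat, rho) {
  rhoHat <- pmin(pmax(rhoHat, 1e-8), 1 - 1e-8)
  sum(rho * log(rho / rhoHat) + (1 - rho) * log((1 - rho) / (1 - rhoHat)))
}

#' Stacked-autoencoder hyperparameters
#'
#' Defaults follow the dimension-reduction design the package implements:
#' hidden widths 600/300/54 (for 1176-dimensional input), L2 weight penalty
#' in the 0.001-0.004 grid (default 0.002), sparsity regularization weight 4
#' with target proportions 0.20/0.15/0.10 per layer, and at most 400
#' pretraining epochs per layer.
#'
#' @param layerDims integer vector of hidden widths, strictly decreasing.
#' @param l2 L2 weight-penalty coefficient (scalar or per layer).
#' @param beta sparsity regularization weight.
#' @param rho per-layer target sparsity proportions.
#' @param maxEpochs maximum pretraining epochs per layer.
#' @param fineTuneEpochs maximum supervised fine-tuning epochs.
#' @param chunk epochs per recorded history point.
#' @return A list of hyperparameters for \code{\link{buildStack}}.
#' @export
aeConfig <- function(layerDims = c(600L, 300L, 54L), l2 = 0.002, beta = 4,
                     rho = c(0.20, 0.15, 0.10), maxEpochs = 400L,
                     fineTuneEpochs = 200L, chunk = 50L) {
  if (any(diff(layerDims) >= 0)) stop("hidden dims must be strictly decreasing")
  if (any(rho <= 0 | rho >= 1)) stop("sparsity proportions must be in (0,1)")
  if (any(l2 < 0) || beta < 0) stop("regularization coefficients must be >= 0")
  list(layerDims = as.integer(layerDims),
       l2 = rep_len(l2, length(layerDims)),
       beta = beta, rho = rep_len(rho, length(layerDims)),
       maxEpochs = as.integer(maxEpochs),
       fineTuneEpochs = as.integer(fineTuneEpochs),
       chunk = as.integer(chunk))
}

## Chunked full-batch quasi-Newton minimization: repeated bounded L-BFGS
## calls of `chunk` iterations, recording the objective at every chunk
## boundary. Each call is a descent, so the history is non-increasing.
.chunked_optim <- function(par, fn, gr, maxEpochs, chunk, record) {
  history <- list(record(par))
  epochs <- 0L
  while (epochs < maxEpochs) {
    it <- min(chunk, maxEpochs - epochs)
    res <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = it))
    if (!is.finite(res$value))
      stop("non-finite training loss; check input scaling")
    par <- res$par
    epochs <- epochs + it
    history[[length(history) + 1L]] <- record(par)
    if (res$convergence == 0) break  # gradient converged before the budget
  }
  list(par = par, history = do.call(rbind, history))
}

.init_mat <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

#' Pretrain one sparse autoencoder layer
#'
#' Minimizes MSE(x, xhat) + lambda * ||W||^2 / 2 + beta * sum_j KL(rho ||
#' rhoHat_j) for a single sigmoid encoder/decoder pair by full-batch
#' quasi-Newton descent, where rhoHat_j is the mean activation of hidden
#' unit j over the batch. The MSE term is the squared reconstruction error
#' summed over output dimensions and averaged over samples (the convention
#' the lambda/beta coefficient scales are calibrated to). Inputs must be
#' scaled to [0,1] (the sigmoid decoder range).
#'
#' @param X numeric matrix, rows x d_in, values in [0,1].
#' @param dHidden hidden-layer width. A warning is issued when the batch has
#'   fewer rows than hidden units.
#' @param l2 L2 weight-penalty coefficient.
#' @param beta sparsity regularization weight.
#' @param rho target sparsity proportion.
#' @param maxEpochs training budget (default 400).
#' @param chunk epochs per recorded history point.
#' @param seed RNG seed for weight initialization.
#' @return list(encoder = list(W, b), decoder = list(W, b), history =
#'   data.frame(epoch, loss, mse, l2, kl)).
#' @export
pretrainLayer <- function(X, dHidden, l2 = 0.002, beta = 4, rho = 0.15,
                          maxEpochs = 400L, chunk = 50L, seed = 1L) {
  dIn <- ncol(X)
  n <- nrow(X)
  if (n < dHidden)
    warning("fewer rows (", n, ") than hidden units (", dHidden, ")")
  sizes <- c(dHidden * dIn, dHidden, dIn * dHidden, dIn)
  unpack <- function(par) {
    s <- cumsum(sizes)
    list(W1 = matrix(par[1:s[1]], dHidden, dIn),
         b1 = par[(s[1] + 1):s[2]],
         W2 = matrix(par[(s[2] + 1):s[3]], dIn, dHidden),
         b2 = par[(s[3] + 1):s[4]])
  }
  forward <- function(p) {
    A1 <- .sigmoid(sweep(X %*% t(p$W1), 2, p$b1, "+"))
    A2 <- .sigmoid(sweep(A1 %*% t(p$W2), 2, p$b2, "+"))
    list(A1 = A1, A2 = A2, rhoHat = colMeans(A1))
  }
  pieces <- function(p, fw) {
    c(mse = sum((fw$A2 - X)^2) / n,
      l2 = 0.5 * l2 * (sum(p$W1^2) + sum(p$W2^2)),
      kl = beta * klSparsity(fw$rhoHat, rho))
  }
  fn <- function(par) {
    p <- unpack(par)
    sum(pieces(p, forward(p)))
  }
  gr <- function(par) {
    p <- unpack(par)
    fw <- forward(p)
    dZ2 <- (2 / n) * (fw$A2 - X) * fw$A2 * (1 - fw$A2)
    gW2 <- t(dZ2) %*% fw$A1 + l2 * p$W2
    gb2 <- colSums(dZ2)
    rhoHat <- pmin(pmax(fw$rhoHat, 1e-8), 1 - 1e-8)
    dRho <- beta * (-rho / rhoHat + (1 - rho) / (1 - rhoHat)) / n
    dA1 <- dZ2 %*% p$W2 + matrix(dRho, n, dHidden, byrow = TRUE)
    dZ1 <- dA1 * fw$A1 * (1 - fw$A1)
    gW1 <- t(dZ1) %*% X + l2 * p$W1
    gb1 <- colSums(dZ1)
    c(as.numeric(gW1), gb1, as.numeric(gW2), gb2)
  }
  par0 <- .with_seed(seed,
    c(as.numeric(.init_mat(dHidden, dIn)), numeric(dHidden),
      as.numeric(.init_mat(dIn, dHidden)), numeric(dIn)))
  record <- function(par) {
    p <- unpack(par)
    pc <- pieces(p, forward(p))
    c(loss = sum(pc), pc)
  }
  fit <- .chunked_optim(par0, fn, gr, maxEpochs, chunk, record)
  p <- unpack(fit$par)
  hist <- as.data.frame(fit$history)
  hist$epoch <- pmin(seq(0L, by = chunk, length.out = nrow(hist)), maxEpochs)
  list(encoder = list(W = p$W1, b = p$b1),
       decoder = list(W = p$W2, b = p$b2),
       history = hist[, c("epoch", "loss", "mse", "l2", "kl")])
}

.encode_matrix <- function(stack, X) {
  Z <- sweep(X, 2, stack@scaler$min, "-")
  Z <- sweep(Z, 2, stack@scaler$range, "/")
  for (layer in stack@encoders)
    Z <- .sigmoid(sweep(Z %*% t(layer$W), 2, layer$b, "+"))
  Z
}

#' Build and fine-tune a stacked sparse autoencoder
#'
#' Greedy pretraining: layer 1 is fit on the min-max-scaled inputs, layer 2
#' on layer-1 codes, layer 3 on layer-2 codes; the encoder stack is then
#' fine-tuned jointly with a softmax classification head by minimizing
#' cross-entropy (plus the same L2 weight penalty). The head is kept for
#' inspection but decoding always goes through an SVM on the embedded codes.
#'
#' @param features a \code{\link{FeatureMatrix}} or numeric matrix of
#'   training rows.
#' @param labels per-row class labels (taken from the FeatureMatrix when
#'   omitted).
#' @param config hyperparameters from \code{\link{aeConfig}}.
#' @param seed RNG seed (weight initialization).
#' @return A \code{\link{StackedAE}}.
#' @export
buildStack <- function(features, labels = NULL, config = aeConfig(),
                       seed = 1L) {
  X <- if (is(features, "FeatureMatrix")) features@values else features
  if (is.null(labels) && is(features, "FeatureMatrix"))
    labels <- features@labels
  labels <- droplevels(as.factor(labels))
  mins <- apply(X, 2, min)
  ranges <- apply(X, 2, max) - mins
  ranges[ranges < .Machine$double.eps] <- 1
  Z <- sweep(sweep(X, 2, mins, "-"), 2, ranges, "/")

  encoders <- list()
  decoders <- list()
  history <- list()
  cur <- Z
  for (i in seq_along(config$layerDims)) {
    fit <- pretrainLayer(cur, config$layerDims[i], l2 = config$l2[i],
                         beta = config$beta, rho = config$rho[i],
                         maxEpochs = config$maxEpochs, chunk = config$chunk,
                         seed = seed + i)
    encoders[[i]] <- fit$encoder
    decoders[[i]] <- fit$decoder
    history[[paste0("layer", i)]] <- fit$history
    cur <- .sigmoid(sweep(cur %*% t(fit$encoder$W), 2, fit$encoder$b, "+"))
  }

  # ---- supervised fine-tuning of the whole encoder + softmax head ----
  K <- nlevels(labels)
  Y <- diag(K)[as.integer(labels), , drop = FALSE]
  dims <- c(ncol(Z), config$layerDims)
  nL <- length(encoders)
  sizes <- unlist(lapply(seq_len(nL), function(i) c(dims[i + 1] * dims[i],
                                                    dims[i + 1])))
  sizes <- c(sizes, K * dims[nL + 1], K)
  offs <- cumsum(c(0, sizes))
  packAll <- function(enc, sm) {
    out <- numeric(offs[length(offs)])
    j <- 1L
    for (i in seq_len(nL)) {
      out[(offs[j] + 1):offs[j + 1]] <- as.numeric(enc[[i]]$W); j <- j + 1L
      out[(offs[j] + 1):offs[j + 1]] <- enc[[i]]$b; j <- j + 1L
    }
    out[(offs[j] + 1):offs[j + 1]] <- as.numeric(sm$W); j <- j + 1L
    out[(offs[j] + 1):offs[j + 1]] <- sm$b
    out
  }
  unpackAll <- function(par) {
    enc <- vector("list", nL)
    j <- 1L
    for (i in seq_len(nL)) {
      W <- matrix(par[(offs[j] + 1):offs[j + 1]], dims[i + 1], dims[i]); j <- j + 1L
      b <- par[(offs[j] + 1):offs[j + 1]]; j <- j + 1L
      enc[[i]] <- list(W = W, b = b)
    }
    W <- matrix(par[(offs[j] + 1):offs[j + 1]], K, dims[nL + 1]); j <- j + 1L
    list(enc = enc, sm = list(W = W, b = par[(offs[j] + 1):offs[j + 1]]))
  }
  ceLoss <- function(par) {
    p <- unpackAll(par)
    A <- Z
    for (l in p$enc) A <- .sigmoid(sweep(A %*% t(l$W), 2, l$b, "+"))
    S <- sweep(A %*% t(p$sm$W), 2, p$sm$b, "+")
    S <- S - apply(S, 1, max)
    P <- exp(S) / rowSums(exp(S))
    wpen <- 0.5 * config$l2[1] *
      (sum(vapply(p$enc, function(l) sum(l$W^2), numeric(1))) + sum(p$sm$W^2))
    -mean(log(pmax(rowSums(P * Y), 1e-12))) + wpen
  }
  ceGrad <- function(par) {
    p <- unpackAll(par)
    acts <- vector("list", nL + 1L)
    acts[[1]] <- Z
    for (i in seq_len(nL))
      acts[[i + 1]] <- .sigmoid(sweep(acts[[i]] %*% t(p$enc[[i]]$W), 2,
                                      p$enc[[i]]$b, "+"))
    S <- sweep(acts[[nL + 1]] %*% t(p$sm$W), 2, p$sm$b, "+")
    S <- S - apply(S, 1, max)
    P <- exp(S) / rowSums(exp(S))
    n <- nrow(Z)
    dS <- (P - Y) / n
    gsmW <- t(dS) %*% acts[[nL + 1]] + config$l2[1] * p$sm$W
    gsmb <- colSums(dS)
    dA <- dS %*% p$sm$W
    genc <- vector("list", nL)
    for (i in rev(seq_len(nL))) {
      dZl <- dA * acts[[i + 1]] * (1 - acts[[i + 1]])
      genc[[i]] <- list(W = t(dZl) %*% acts[[i]] + config$l2[1] * p$enc[[i]]$W,
                        b = colSums(dZl))
      dA <- dZl %*% p$enc[[i]]$W
    }
    packAll(genc, list(W = gsmW, b = gsmb))
  }
  sm0 <- .with_seed(seed + 100L,
                    list(W = .init_mat(K, dims[nL + 1]), b = numeric(K)))
  par0 <- packAll(encoders, sm0)
  fit <- .chunked_optim(par0, ceLoss, ceGrad, config$fineTuneEpochs,
                        config$chunk,
                        function(par) c(loss = ceLoss(par)))
  tuned <- unpackAll(fit$par)
  hist <- as.data.frame(fit$history)
  hist$epoch <- pmin(seq(0L, by = config$chunk, length.out = nrow(hist)),
                     config$fineTuneEpochs)
  history$finetune <- hist[, c("epoch", "loss")]

  cfg <- config
  cfg$inputDim <- ncol(Z)
  cfg$classes <- levels(labels)
  new("StackedAE", encoders = tuned$enc, decoders = decoders,
      softmax = tuned$sm, scaler = list(min = mins, range = ranges),
      config = cfg, history = history)
}

#' Encode features through a stacked autoencoder
#'
#' Deterministic, label-free forward pass: the training-fit min-max scaling
#' is applied, then each sigmoid encoder layer in turn. Output values lie in
#' (0,1). When the code width is a multiple of 6, the result is returned as
#' a \code{FeatureMatrix} whose pseudo-sensors ("AE01", ...) each own one
#' 6-column block, so it can flow through the same decoding interfaces as
#' sensor features.
#'
#' @param stack a \code{\link{StackedAE}}.
#' @param features \code{FeatureMatrix} or matrix with the training input
#'   width.
#' @return A \code{FeatureMatrix} of codes (labels carried through).
#' @export
encodeFeatures <- function(stack, features) {
  X <- if (is(features, "FeatureMatrix")) features@values else features
  if (ncol(X) != stack@config$inputDim)
    stop("feature width ", ncol(X), " does not match autoencoder input ",
         stack@config$inputDim)
  Z <- .encode_matrix(stack, X)
  dCode <- ncol(Z)
  if (dCode %% 6L != 0L)
    stop("code width must be a multiple of 6 to form a FeatureMatrix")
  pseudo <- sprintf("AE%02d", seq_len(dCode / 6L))
  key <- .make_column_key(pseudo)
  colnames(Z) <- paste(key$sensor, key$band, sep = "_")
  labels <- if (is(features, "FeatureMatrix")) features@labels
            else factor(rep(NA_character_, nrow(X)))
  new("FeatureMatrix", values = Z, sensorIds = pseudo, labels = labels,
      columnKey = key)
}

#' Cross-validated decoding through the autoencoder embedding
#'
#' Per fold, the stacked autoencoder (scaling, pretraining and fine-tuning)
#' is fit on the training rows only, both splits are encoded, and the
#' polynomial SVM is trained and scored on the codes — so no test row ever
#' influences the embedding. \code{singleSplit = TRUE} instead fits one
#' autoencoder on the first fold's training split and scores only that
#' fold.
#'
#' @param features a \code{\link{FeatureMatrix}}.
#' @param aeCfg hyperparameters from \code{\link{aeConfig}}.
#' @param config a \code{\link{DecoderConfig}}.
#' @param foldAssign optional frozen fold assignment.
#' @param seed RNG seed for the autoencoder fits.
#' @param singleSplit fit the autoencoder once on fold 1's training split.
#' @return A \code{\link{CVResult}}.
#' @export
aePipelineEval <- function(features, aeCfg = aeConfig(),
                           config = decoderConfig(), foldAssign = NULL,
                           seed = 1L, singleSplit = FALSE) {
  y <- droplevels(features@labels)
  if (is.null(foldAssign))
    foldAssign <- makeFolds(y, config@folds, config@seed)
  foldIds <- sort(unique(foldAssign))
  if (singleSplit) foldIds <- foldIds[1]
  lev <- levels(y)
  conf <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  acc <- numeric(length(foldIds))
  for (i in seq_along(foldIds)) {
    te <- foldAssign == foldIds[i]
    Xtr <- features@values[!te, , drop = FALSE]
    Xte <- features@values[te, , drop = FALSE]
    stack <- buildStack(Xtr, y[!te], aeCfg, seed = seed + i)
    Ztr <- .encode_matrix(stack, Xtr)
    Zte <- .encode_matrix(stack, Xte)
    sc <- .fit_scaler(Ztr)
    fit <- e1071::svm(.apply_scaler(Ztr, sc), y[!te], kernel = "polynomial",
                      degree = config@degree, gamma = 1 / ncol(Ztr),
                      coef0 = 0, cost = config@cost, scale = FALSE)
    pred <- predict(fit, .apply_scaler(Zte, sc))
    acc[i] <- 100 * mean(pred == y[te])
    conf[] <- conf + table(factor(y[te], lev), factor(pred, lev))
  }
  new("CVResult", foldAccuracies = acc, meanAccuracy = mean(acc),
      sd = if (length(acc) > 1) stats::sd(acc) else 0, confusion = conf,
      foldAssignment = as.integer(foldAssign))
}
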