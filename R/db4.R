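#' @include AllClasses.R
NULL

## Daubechies-4 (8-tap, 4 vanishing moments) filter bank. Synthesis low-pass
## is the canonical coefficient sequence; the rest follow from the
## quadrature-mirror relations of an orthogonal wavelet.
.db4_rec_lo <- c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
                 -0.027983769416859854, -0.18703481171909309,
                 0.030841381835560764, 0.0328830116668852,
                 -0.010597401785069032)
.db4_dec_lo <- rev(.db4_rec_lo)
.db4_dec_hi <- .db4_rec_lo * rep(c(-1, 1), 4L)
.db4_rec_hi <- rev(.db4_dec_hi)
.db4_len <- 8L

## All transforms operate column-wise on a samples x signals matrix; the
## 8-tap convolutions are written as eight shifted scaled adds so a whole
## epoch set is transformed in one vectorized pass.

## One analysis step: symmetric (half-sample) boundary extension by F-1 on
## each side, convolution, downsampling by 2. Output length (n + F - 1) %/% 2.
.dwt_step_mat <- function(X, filt) {
  Fl <- .db4_len
  n <- nrow(X)
  Xe <- rbind(X[(Fl - 1L):1L, , drop = FALSE], X,
              X[n:(n - Fl + 2L), , drop = FALSE])
  outLen <- (n + Fl - 1L) %/% 2L
  idx <- Fl + 1L + 2L * (seq_len(outLen) - 1L)
  Z <- matrix(0, outLen, ncol(X))
  for (j in seq_len(Fl))
    Z <- Z + filt[j] * Xe[idx - j + 1L, , drop = FALSE]
  Z
}

## One synthesis step: zero-upsample both branches, convolve with the
## reconstruction filters, and keep the outLen samples after the F-2
## transition region.
.idwt_step_mat <- function(CA, CD, outLen) {
  Fl <- .db4_len
  L <- nrow(CA)
  m <- ncol(CA)
  pad <- function(C) {
    U <- matrix(0, 2L * L + 2L * (Fl - 1L), m)
    U[Fl - 1L + seq(1L, 2L * L, 2L), ] <- C
    U
  }
  UA <- pad(CA)
  UD <- pad(CD)
  kk <- (Fl - 1L):(Fl - 2L + outLen)
  Z <- matrix(0, outLen, m)
  for (j in seq_len(Fl)) {
    rows <- kk - j + Fl
    Z <- Z + .db4_rec_lo[j] * UA[rows, , drop = FALSE] +
             .db4_rec_hi[j] * UD[rows, , drop = FALSE]
  }
  Z
}

## Multilevel decomposition of a samples x signals matrix.
.db4_decompose_mat <- function(X, levels) {
  details <- vector("list", levels)
  lens <- integer(levels)
  cur <- X
  for (l in seq_len(levels)) {
    lens[l] <- nrow(cur)
    details[[l]] <- .dwt_step_mat(cur, .db4_dec_hi)
    cur <- .dwt_step_mat(cur, .db4_dec_lo)
  }
  names(details) <- paste0("d", seq_len(levels))
  list(approx = cur, details = details, lengths = lens)
}

## Reconstruct a single branch ("d3".."dL" or "aL") back to signal length.
.db4_branch_mat <- function(dec, branch) {
  levels <- length(dec$details)
  if (startsWith(branch, "a")) {
    Z <- .idwt_step_mat(dec$approx,
                        matrix(0, nrow(dec$approx), ncol(dec$approx)),
                        dec$lengths[levels])
    from <- levels - 1L
  } else {
    l <- as.integer(substring(branch, 2))
    Z <- .idwt_step_mat(matrix(0, nrow(dec$details[[l]]),
                               ncol(dec$details[[l]])),
                        dec$details[[l]], dec$lengths[l])
    from <- l - 1L
  }
  if (from >= 1L)
    for (k in from:1L)
      Z <- .idwt_step_mat(Z, matrix(0, nrow(Z), ncol(Z)), dec$lengths[k])
  Z
}

## RMS of the six band reconstructions for every column of X: 6 x m matrix
## in canonical band order (d3..d7, a7 = high-gamma..delta).
.wavelet_rms_mat <- function(X, levels = 7L) {
  dec <- .db4_decompose_mat(X, levels)
  branches <- c(paste0("d", 3:levels), paste0("a", levels))
  out <- matrix(0, 6L, ncol(X))
  for (i in seq_along(branches))
    out[i, ] <- sqrt(colMeans(.db4_branch_mat(dec, branches[i])^2))
  out
}

#' Multilevel db4 discrete wavelet decomposition
#'
#' Decomposes a 1-D signal into detail coefficients d1..dL and the final
#' approximation aL using the Daubechies-4 wavelet with symmetric boundary
#' extension. Coefficient layout and lengths follow the conventional pyramid
#' algorithm; \code{\link{db4Reconstruct}} inverts it to machine precision.
#'
#' @param x numeric vector, length >= 2^levels.
#' @param levels integer decomposition depth (default 7).
#' @return List with \code{approx} (aL), \code{details} (list d1..dL) and
#'   \code{lengths} (signal length entering each level, needed to invert).
#' @export
#' @examples
#' dec <- db4Decompose(sin(2 * pi * 40 * seq(0, 1, length.out = 1000)))
#' lengths(dec$details)
db4Decompose <- function(x, levels = 7L) {
  if (!is.numeric(x) || length(x) < 2^levels)
    stop("signal too short for ", levels, "-level decomposition")
  dec <- .db4_decompose_mat(matrix(as.numeric(x), ncol = 1), levels)
  list(approx = as.numeric(dec$approx),
       details = lapply(dec$details, as.numeric),
       lengths = dec$lengths)
}

#' Inverse multilevel db4 transform
#'
#' Reconstructs a signal from a (possibly modified) decomposition produced
#' by \code{\link{db4Decompose}}. Zeroing all branches but one yields the
#' single-branch band reconstruction used for band-power features; by
#' linearity the branch reconstructions sum to the original signal.
#'
#' @param dec list as returned by \code{db4Decompose}.
#' @return Numeric vector of the original length.
#' @export
db4Reconstruct <- function(dec) {
  cur <- matrix(dec$approx, ncol = 1)
  for (l in rev(seq_along(dec$details)))
    cur <- .idwt_step_mat(cur, matrix(dec$details[[l]], ncol = 1),
                          dec$lengths[l])
  as.numeric(cur)
}

#' Single-branch band reconstructions of a 1 kHz signal
#'
#' Seven-level db4 decomposition with the first two detail levels (d1, d2;
#' 125-500 Hz at 1 kHz sampling) discarded as noise, and each remaining
#' branch (d3..d7 and a7) reconstructed alone back to the original signal
#' length. The six reconstructions correspond to the canonical bands
#' high-gamma, gamma, beta, alpha, theta and delta (see
#' \code{\link{bandTable}}).
#'
#' @param x numeric vector, length >= 128, nominally sampled at 1 kHz.
#' @param levels integer decomposition depth (default 7).
#' @return Numeric matrix, length(x) x 6, columns named by band.
#' @export
#' @examples
#' b <- waveletBands(rnorm(1000))
#' colnames(b)
waveletBands <- function(x, levels = 7L) {
  if (!is.numeric(x) || length(x) < 2^levels)
    stop("signal too short for ", levels, "-level decomposition")
  dec <- .db4_decompose_mat(matrix(as.numeric(x), ncol = 1), levels)
  branches <- c(paste0("d", 3:levels), paste0("a", levels))
  out <- matrix(0, length(x), 6L, dimnames = list(NULL, bandNames()))
  for (i in seq_along(branches))
    out[, i] <- .db4_branch_mat(dec, branches[i])
  out
}

#' Root-mean-square amplitude
#'
#' @param x non-empty numeric vector.
#' @return sqrt(mean(x^2)), a non-negative scalar.
#' @export
#' @examples
#' rmsValue(c(3, 4))  # sqrt((9 + 16) / 2)
rmsValue <- function(x) {
  if (length(x) == 0) stop("rmsValue: empty window")
  sqrt(mean(x^2))
}
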