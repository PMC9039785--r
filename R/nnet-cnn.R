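#' @include AllClasses.R AllGenerics.R nnet-ff.R
NULL

# linear indices turning a W x C matrix into its L x (F*C) sliding-window
# ("im2col") representation, L = W - F + 1; column j corresponds to kernel
# entry (u, c) with u = (j-1) %% F + 1, c = (j-1) %/% F + 1, matching the
# column-major flattening of an F x C kernel
im2colIndex <- function(W, F, C) {
  if (F > W) stop(sprintf("kernel length F = %d exceeds input length W = %d",
                          F, W))
  u <- rep(seq_len(F), C)
  cc <- rep(seq_len(C), each = F)
  outer(0:(W - F), u + (cc - 1L) * W, "+")
}

#' One-dimensional valid cross-correlation over channels
#'
#' Computes, for a W x C segment S and an F x C kernel K,
#' \deqn{(K * S)(i) = \sum_{c=1}^{C} \sum_{u=1}^{F} K(u, c)\, S(i+u-1, c),
#'   \qquad 1 \le i \le W - F + 1,}
#' the channel-summed sliding dot product applied by a 1-D convolution
#' layer, plus an optional bias.
#'
#' @param S numeric W x C matrix.
#' @param K numeric F x C kernel, `F <= W`.
#' @param bias scalar added to every output entry.
#' @return numeric vector of length `W - F + 1`.
#' @examples
#' conv1dValid(matrix(1:8, 8, 1), matrix(c(1, 1, 1), 3, 1))
#' @export
conv1dValid <- function(S, K, bias = 0) {
  stopifnot(is.matrix(S), is.matrix(K), ncol(S) == ncol(K))
  idx <- im2colIndex(nrow(S), nrow(K), ncol(S))
  as.numeric(matrix(S[as.vector(idx)], nrow(idx)) %*% as.vector(K)) + bias
}

#' One-dimensional max pooling
#'
#' Slides a window of `WM` entries with the given stride over a vector and
#' keeps the maximum of each window; the output has
#' `floor((L - WM) / stride) + 1` entries.
#'
#' @param v numeric vector.
#' @param WM pooling window size (default 3).
#' @param stride step between windows (default 2).
#' @return numeric vector of pooled maxima.
#' @examples
#' maxPool1d(1:10, WM = 3, stride = 2)
#' @export
maxPool1d <- function(v, WM = 3L, stride = 2L) {
  L <- length(v)
  if (L < WM) stop("input shorter than the pooling window")
  nOut <- (L - WM) %/% stride + 1L
  starts <- (seq_len(nOut) - 1L) * stride
  vapply(starts, function(s) max(v[(s + 1L):(s + WM)]), numeric(1))
}

#' Build the convolutional network configuration
#'
#' Fixes the architecture for input segments of size (W, C): a convolution
#' layer with `nFilters` filters of length `F1 = floor(W / 2)` and ReLU
#' activation, max pooling (window 3, stride 2), a second convolution with
#' `nFilters` filters of length `F2 = 10`, flattening to d units, a dense
#' layer of 100 tanh neurons, and a two-neuron softmax output. Weights are
#' initialised from a truncated normal (SD 0.05, truncation 2 SD) and the
#' convolution biases start at the constant `biasConst`.
#'
#' @param W segment length in time points.
#' @param C number of channels.
#' @param nFilters filters per convolution layer (default 70).
#' @param F2 kernel length of the second convolution (default 10).
#' @param WM,poolStride max-pooling window and stride (defaults 3 and 2).
#' @param denseWidth width of the tanh layer (default 100).
#' @param epochs,lr,batchSize training schedule (defaults 10, 1e-4, 32).
#' @param initSD,initTrunc truncated-normal initialisation parameters.
#' @param biasConst constant initial convolution bias (default 0.1).
#' @return a `CNNConfig` list (layer sizes, flattened dimension `d`,
#'   precomputed index maps).
#' @export
cnnBuild <- function(W, C, nFilters = 70L, F2 = 10L, WM = 3L,
                     poolStride = 2L, denseWidth = 100L, epochs = 10L,
                     lr = 1e-4, batchSize = 32L, initSD = 0.05,
                     initTrunc = 2, biasConst = 0.1) {
  W <- as.integer(W); C <- as.integer(C)
  F1 <- W %/% 2L
  if (F1 < 1L) stop("W too small: first kernel would be empty")
  L1 <- W - F1 + 1L
  if (L1 < WM)
    stop(sprintf("W = %d too small: conv output %d < pooling window %d",
                 W, L1, WM))
  L2 <- (L1 - WM) %/% poolStride + 1L
  if (L2 < F2)
    stop(sprintf(paste0("W = %d too small: pooled length %d < second ",
                        "kernel length %d"), W, L2, F2))
  L3 <- L2 - F2 + 1L
  structure(list(
    W = W, C = C, nFilters = as.integer(nFilters), F1 = F1,
    F2 = as.integer(F2), WM = as.integer(WM),
    poolStride = as.integer(poolStride), denseWidth = as.integer(denseWidth),
    L1 = L1, L2 = L2, L3 = L3, d = L3 * as.integer(nFilters),
    epochs = as.integer(epochs), lr = lr, batchSize = as.integer(batchSize),
    initSD = initSD, initTrunc = initTrunc, biasConst = biasConst,
    idx1 = im2colIndex(W, F1, C),
    idx2 = im2colIndex(L2, as.integer(F2), as.integer(nFilters)),
    poolStarts = (seq_len(L2) - 1L) * as.integer(poolStride)
  ), class = "CNNConfig")
}

#' @export
print.CNNConfig <- function(x, ...) {
  cat(sprintf(
    paste0("CNNConfig: (%d x %d) -> conv(%d, F1=%d) -> pool(%d, %d) -> ",
           "conv(%d, F2=%d) -> flatten(%d) -> dense(%d, tanh) -> softmax\n"),
    x$W, x$C, x$nFilters, x$F1, x$WM, x$poolStride, x$nFilters, x$F2,
    x$d, x$denseWidth))
  invisible(x)
}

#' Convolutional network classifier for raw segments
#'
#' A one-dimensional convolutional network trained end-to-end on raw
#' (standardized) multichannel segments; see [cnnBuild()] for the
#' architecture and [fitCNN()] for training.
#'
#' @slot params list of kernels, biases and dense weights.
#' @slot config the `CNNConfig` used.
#' @slot channelNames training channel names.
#' @export
setClass("CNNClassifier",
  representation(params = "list", config = "list",
                 channelNames = "character")
)

# forward pass over a list of W x C matrices; keeps intermediates if train
cnnForward <- function(params, cfg, mats, train = FALSE) {
  n <- length(mats)
  Xf <- matrix(0, n, cfg$d)
  inter <- if (train) vector("list", n) else NULL
  nf <- cfg$nFilters
  for (i in seq_len(n)) {
    S <- mats[[i]]
    X1 <- matrix(S[as.vector(cfg$idx1)], cfg$L1)
    Z1 <- sweep(X1 %*% params$K1, 2L, params$b1, "+")
    A1 <- pmax(Z1, 0)
    # max pool each filter column: window WM, given stride, with argmax
    pooled <- matrix(0, cfg$L2, nf)
    amax <- matrix(1L, cfg$L2, nf)
    for (w in seq_len(cfg$WM)) {
      slice <- A1[cfg$poolStarts + w, , drop = FALSE]
      if (w == 1L) {
        pooled <- slice
      } else {
        upd <- slice > pooled
        amax[upd] <- w
        pooled[upd] <- slice[upd]
      }
    }
    X2 <- matrix(pooled[as.vector(cfg$idx2)], cfg$L3)
    Z2 <- sweep(X2 %*% params$K2, 2L, params$b2, "+")
    A2 <- pmax(Z2, 0)
    Xf[i, ] <- as.vector(A2)
    if (train)
      inter[[i]] <- list(X1 = X1, Z1pos = Z1 > 0, amax = amax,
                         X2 = X2, Z2pos = Z2 > 0)
  }
  H <- tanh(sweep(Xf %*% params$Wd, 2L, params$bd, "+"))
  logits <- sweep(H %*% params$Wo, 2L, params$bo, "+")
  list(Xf = Xf, H = H, logits = logits, probs = softmaxRows(logits),
       inter = inter)
}

# accumulate values into a zero vector of length n at (repeating) indices
scatterAdd <- function(n, idx, vals) {
  s <- rowsum(as.numeric(vals), group = as.integer(idx))
  out <- numeric(n)
  out[as.integer(rownames(s))] <- s
  out
}

#' Train the convolutional network
#'
#' Fits the [cnnBuild()] architecture with the Adam optimizer minimising
#' categorical cross-entropy (learning rate 1e-4, 10 epochs by default).
#' Deterministic given the seed.
#'
#' @param segments list of \linkS4class{Segment} objects, or of plain
#'   W x C matrices (then `labels` is required). All segments must share
#'   the training window length W.
#' @param labels optional 0/1 vector overriding the segment group labels.
#' @param config a `CNNConfig`; built automatically from the first segment
#'   when omitted.
#' @param seed integer seed for initialisation and batch order.
#' @return a \linkS4class{CNNClassifier}.
#' @export
fitCNN <- function(segments, labels = NULL, config = NULL, seed = 1L) {
  mats <- lapply(segments, function(s) if (is(s, "Segment")) s@data else s)
  if (is.null(labels))
    labels <- vapply(segments, function(s) s@group, integer(1))
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  Ws <- vapply(mats, nrow, integer(1))
  if (length(unique(Ws)) != 1L)
    stop("all segments must share the window length")
  if (is.null(config)) config <- cnnBuild(Ws[1], ncol(mats[[1]]))
  cfg <- config
  if (Ws[1] != cfg$W || ncol(mats[[1]]) != cfg$C)
    stop("segment shape does not match the network configuration")
  Y <- cbind(1 - labels, labels)
  withSeed(seed, {
    nf <- cfg$nFilters
    params <- list(
      K1 = matrix(rtruncnorm0(cfg$F1 * cfg$C * nf, cfg$initSD,
                              cfg$initTrunc), cfg$F1 * cfg$C),
      b1 = rep(cfg$biasConst, nf),
      K2 = matrix(rtruncnorm0(cfg$F2 * nf * nf, cfg$initSD, cfg$initTrunc),
                  cfg$F2 * nf),
      b2 = rep(cfg$biasConst, nf),
      Wd = matrix(rtruncnorm0(cfg$d * cfg$denseWidth, cfg$initSD,
                              cfg$initTrunc), cfg$d),
      bd = rep(0, cfg$denseWidth),
      Wo = matrix(rtruncnorm0(cfg$denseWidth * 2L, cfg$initSD,
                              cfg$initTrunc), cfg$denseWidth),
      bo = rep(0, 2L))
    state <- adamInit(params)
    n <- length(mats)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (bs in split(ord, ceiling(seq_along(ord) / cfg$batchSize))) {
        fwd <- cnnForward(params, cfg, mats[bs], train = TRUE)
        if (!all(is.finite(fwd$probs))) stop("non-finite training loss")
        nb <- length(bs)
        delta <- (fwd$probs - Y[bs, , drop = FALSE]) / nb
        grads <- list(Wo = crossprod(fwd$H, delta), bo = colSums(delta))
        dH <- (delta %*% t(params$Wo)) * (1 - fwd$H^2)
        grads$Wd <- crossprod(fwd$Xf, dH)
        grads$bd <- colSums(dH)
        dXf <- dH %*% t(params$Wd)
        dK1 <- params$K1 * 0; db1 <- params$b1 * 0
        dK2 <- params$K2 * 0; db2 <- params$b2 * 0
        for (j in seq_len(nb)) {
          iv <- fwd$inter[[j]]
          dA2 <- matrix(dXf[j, ], cfg$L3, nf)
          dZ2 <- dA2 * iv$Z2pos
          dK2 <- dK2 + crossprod(iv$X2, dZ2)
          db2 <- db2 + colSums(dZ2)
          dX2 <- dZ2 %*% t(params$K2)
          dPooled <- matrix(
            scatterAdd(cfg$L2 * nf, cfg$idx2, dX2), cfg$L2, nf)
          # route pooled gradients back to the winning pre-pool positions
          rows <- cfg$poolStarts + iv$amax
          lin <- rows + (col(iv$amax) - 1L) * cfg$L1
          dA1 <- matrix(scatterAdd(cfg$L1 * nf, lin, dPooled), cfg$L1, nf)
          dZ1 <- dA1 * iv$Z1pos
          dK1 <- dK1 + crossprod(iv$X1, dZ1)
          db1 <- db1 + colSums(dZ1)
        }
        grads$K1 <- dK1; grads$b1 <- db1
        grads$K2 <- dK2; grads$b2 <- db2
        grads <- grads[names(params)]
        upd <- adamStep(params, grads, state, cfg$lr)
        params <- upd$params
        state <- upd$state
      }
    }
    new("CNNClassifier", params = params, config = unclass(cfg),
        channelNames = colnames(mats[[1]]) %||% character())
  })
}

#' Class probabilities of the convolutional network
#'
#' @param model a \linkS4class{CNNClassifier}.
#' @param segments list of \linkS4class{Segment}s or W x C matrices.
#' @return n x 2 matrix of softmax probabilities (columns: class 0, 1).
#' @export
cnnProbabilities <- function(model, segments) {
  mats <- lapply(segments, function(s) if (is(s, "Segment")) s@data else s)
  cnnForward(model@params, model@config, mats)$probs
}

#' @rdname classifier-contract
#' @export
setMethod("predictClass", "CNNClassifier", function(model, newdata, ...) {
  pr <- cnnProbabilities(model, newdata)
  as.integer(pr[, 2L] > pr[, 1L])
})

#' @rdname classifier-contract
#' @export
setMethod("decisionScore", "CNNClassifier", function(model, newdata, ...) {
  pr <- cnnProbabilities(model, newdata)
  pr[, 2L] - pr[, 1L]
})
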