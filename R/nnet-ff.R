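#' @include AllClasses.R AllGenerics.R classifiers-lda.R
NULL

# --- Adam optimizer (Kingma & Ba defaults beta1=.9, beta2=.999, eps=1e-8) ---

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (k in names(params)) {
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * grads[[k]]
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - b1^state$t)
    vhat <- state$v[[k]] / (1 - b2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# mean categorical cross-entropy of softmax probabilities
crossEntropy <- function(probs, yOneHot) {
  -mean(rowSums(yOneHot * log(pmax(probs, 1e-12))))
}

#' Feedforward neural network classifier
#'
#' A fully-connected network for binary classification: two hidden layers
#' of 100 neurons with ReLU activation and a two-neuron softmax output
#' \eqn{\psi(x)_j = e^{x_j} / (e^{x_1} + e^{x_2})}, trained with the Adam
#' optimizer minimising categorical cross-entropy (10 epochs, learning
#' rate 0.01 by default). Prediction is the argmax of the two output
#' probabilities.
#'
#' @slot params list of weight matrices / bias vectors per layer.
#' @slot hidden integer vector of hidden-layer widths.
#' @slot featureNames training feature names.
#' @slot config training configuration snapshot.
#' @export
setClass("FFClassifier",
  representation(params = "list", hidden = "integer",
                 featureNames = "character", config = "list")
)

ffForward <- function(params, X, nHidden) {
  acts <- list()
  H <- X
  for (l in seq_len(nHidden)) {
    Z <- sweep(H %*% params[[paste0("W", l)]], 2L,
               params[[paste0("b", l)]], "+")
    H <- pmax(Z, 0)
    acts[[l]] <- list(Z = Z, H = H)
  }
  logits <- sweep(H %*% params$Wout, 2L, params$bout, "+")
  list(acts = acts, logits = logits, probs = softmaxRows(logits))
}

#' Fit the feedforward network
#'
#' @param fs a \linkS4class{LabeledFeatureSet} with both classes present.
#' @param hidden hidden-layer widths (default `c(100, 100)`).
#' @param epochs training epochs (default 10).
#' @param lr Adam learning rate (default 0.01).
#' @param batchSize minibatch size (default 32).
#' @param initSD SD of the truncated-normal weight initialisation
#'   (truncation at 2 SD).
#' @param seed integer seed; initialisation and batch order are
#'   deterministic given it.
#' @return an \linkS4class{FFClassifier}.
#' @export
fitFF <- function(fs, hidden = c(100L, 100L), epochs = 10L, lr = 0.01,
                  batchSize = 32L, initSD = 0.05, seed = 1L) {
  stopifnot(is(fs, "LabeledFeatureSet"))
  X <- fs@features
  y <- fs@labels
  if (length(unique(y)) < 2L) stop("both classes must be present")
  sizes <- c(ncol(X), hidden, 2L)
  nHidden <- length(hidden)
  Y <- cbind(1 - y, y)  # one-hot: column 1 = class 0, column 2 = class 1
  withSeed(seed, {
    params <- list()
    for (l in seq_len(nHidden)) {
      params[[paste0("W", l)]] <- matrix(
        rtruncnorm0(sizes[l] * sizes[l + 1L], initSD), sizes[l])
      params[[paste0("b", l)]] <- rep(0, sizes[l + 1L])
    }
    params$Wout <- matrix(rtruncnorm0(sizes[nHidden + 1L] * 2L, initSD),
                          sizes[nHidden + 1L])
    params$bout <- rep(0, 2L)
    state <- adamInit(params)
    n <- nrow(X)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (bs in split(ord, ceiling(seq_along(ord) / batchSize))) {
        Xb <- X[bs, , drop = FALSE]
        Yb <- Y[bs, , drop = FALSE]
        fwd <- ffForward(params, Xb, nHidden)
        if (!all(is.finite(fwd$probs))) stop("non-finite training loss")
        grads <- list()
        delta <- (fwd$probs - Yb) / nrow(Xb)
        Hprev <- if (nHidden) fwd$acts[[nHidden]]$H else Xb
        grads$Wout <- crossprod(Hprev, delta)
        grads$bout <- colSums(delta)
        back <- delta %*% t(params$Wout)
        for (l in rev(seq_len(nHidden))) {
          back <- back * (fwd$acts[[l]]$Z > 0)
          Hin <- if (l > 1L) fwd$acts[[l - 1L]]$H else Xb
          grads[[paste0("W", l)]] <- crossprod(Hin, back)
          grads[[paste0("b", l)]] <- colSums(back)
          if (l > 1L) back <- back %*% t(params[[paste0("W", l)]])
        }
        upd <- adamStep(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
      }
    }
    new("FFClassifier", params = params, hidden = as.integer(hidden),
        featureNames = colnames(X),
        config = list(epochs = epochs, lr = lr, batchSize = batchSize,
                      initSD = initSD, seed = seed))
  })
}

#' Class probabilities of a feedforward network
#'
#' @param model an \linkS4class{FFClassifier}.
#' @param newdata feature matrix.
#' @return n x 2 matrix of softmax probabilities (columns: class 0, 1).
#' @export
ffProbabilities <- function(model, newdata) {
  newdata <- asFeatureMatrix(newdata, model@featureNames)
  ffForward(model@params, newdata, length(model@hidden))$probs
}

#' @rdname classifier-contract
#' @export
setMethod("predictClass", "FFClassifier", function(model, newdata, ...) {
  pr <- ffProbabilities(model, newdata)
  as.integer(pr[, 2L] > pr[, 1L])
})

#' @rdname classifier-contract
#' @export
setMethod("decisionScore", "FFClassifier", function(model, newdata, ...) {
  pr <- ffProbabilities(model, newdata)
  pr[, 2L] - pr[, 1L]
})
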