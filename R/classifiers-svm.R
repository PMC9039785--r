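#' @include AllClasses.R AllGenerics.R classifiers-lda.R
NULL

#' Soft-margin support vector classifier
#'
#' Wraps a libsvm fit (via e1071) of the soft-margin problem
#' \deqn{\min_{\beta,\beta_0} \tfrac12 \|\beta\|^2 + C \sum_i \xi_i
#'   \quad \text{s.t.} \quad y_i(x_i'\beta + \beta_0) \ge 1 - \xi_i,
#'   \ \xi_i \ge 0,}
#' with classes coded -1/+1 (class 0 maps to -1). The fitted decision
#' function is \eqn{D(x) = \sum_{i \in \Omega} \alpha_i y_i K(x, x_i) +
#' \beta_0} over the support set \eqn{\Omega}; prediction is its sign.
#' For the linear kernel the primal weight vector
#' \eqn{\beta = \sum \alpha_i y_i x_i} and the margin \eqn{M = 1/\|\beta\|}
#' are exposed; [svmKKT()] verifies the Karush-Kuhn-Tucker conditions of
#' every fit.
#'
#' @slot fit the underlying e1071 model.
#' @slot orientation +1/-1 sign aligning libsvm's internal decision values
#'   with the package convention (positive = class 1).
#' @slot kernel `"linear"` or `"radial"`.
#' @slot cost,gamma hyperparameters (gamma only for the radial kernel).
#' @slot beta primal weights (linear kernel; empty otherwise).
#' @slot beta0 intercept.
#' @slot margin 1/||beta|| (linear kernel; NA otherwise).
#' @slot featureNames training feature names.
#' @export
setClass("SVMClassifier",
  representation(fit = "ANY", orientation = "numeric", kernel = "character",
                 cost = "numeric", gamma = "numeric", beta = "numeric",
                 beta0 = "numeric", margin = "numeric",
                 featureNames = "character")
)

#' Fit a support vector classifier
#'
#' Defaults follow the study configuration: cost `C = 1` and, for the
#' radial kernel, `gamma = 1 / (p * Var(X))` with `Var(X)` the pooled
#' (population) variance of all feature-matrix entries.
#'
#' @param fs a \linkS4class{LabeledFeatureSet} with both classes present.
#' @param kernel `"linear"` or `"radial"`.
#' @param cost the cost parameter C (> 0).
#' @param gamma radial-kernel width; default `1 / (p * Var(X))`.
#' @return an \linkS4class{SVMClassifier}.
#' @export
fitSVM <- function(fs, kernel = c("linear", "radial"), cost = 1,
                   gamma = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(is(fs, "LabeledFeatureSet"))
  X <- fs@features
  y <- fs@labels
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (is.null(gamma)) {
    v <- mean(X^2) - mean(X)^2  # pooled population variance of all entries
    gamma <- if (v > 0) 1 / (ncol(X) * v) else 1
  }
  ypm <- factor(ifelse(y == 1L, 1L, -1L), levels = c(-1L, 1L))
  fit <- e1071::svm(X, ypm, scale = FALSE, type = "C-classification",
                    kernel = kernel, cost = cost, gamma = gamma)
  # libsvm's decision values are positive for its internally-first class;
  # align so positive means class +1
  dv <- attr(stats::predict(fit, X[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  firstClass <- strsplit(colnames(dv), "/")[[1]][1]
  orientation <- if (firstClass == "1") 1 else -1
  beta <- numeric(0)
  margin <- NA_real_
  if (kernel == "linear") {
    beta <- orientation * as.numeric(crossprod(fit$SV, fit$coefs))
    names(beta) <- colnames(X)
    margin <- 1 / sqrt(sum(beta^2))
  }
  new("SVMClassifier", fit = fit, orientation = orientation,
      kernel = kernel, cost = cost, gamma = gamma, beta = beta,
      beta0 = orientation * (-fit$rho), margin = margin,
      featureNames = colnames(X))
}

#' @rdname classifier-contract
#' @export
setMethod("decisionScore", "SVMClassifier", function(model, newdata, ...) {
  newdata <- asFeatureMatrix(newdata, model@featureNames)
  dv <- attr(stats::predict(model@fit, newdata, decision.values = TRUE),
             "decision.values")
  model@orientation * as.numeric(dv)
})

#' @rdname classifier-contract
#' @export
setMethod("predictClass", "SVMClassifier", function(model, newdata, ...) {
  as.integer(decisionScore(model, newdata) > 0)
})

#' Karush-Kuhn-Tucker diagnostics of a fitted linear or radial SVM
#'
#' Checks, on the training data, the stationarity pattern of the dual
#' solution: unbounded support vectors (0 < alpha < C) must lie on the
#' margin (`y D(x) = 1`), bounded ones (alpha = C) inside or beyond it
#' (`y D(x) <= 1`), and non-support points outside (`y D(x) >= 1`).
#'
#' @param model an \linkS4class{SVMClassifier}.
#' @param fs the training \linkS4class{LabeledFeatureSet}.
#' @return list with `maxViolation` (largest constraint violation, 0 when
#'   all conditions hold), `marginIdentityError` (|M - 1/||beta||| for the
#'   linear kernel, else NA) and the per-point `yD` values.
#' @export
svmKKT <- function(model, fs) {
  stopifnot(is(model, "SVMClassifier"), is(fs, "LabeledFeatureSet"))
  X <- fs@features
  ypm <- ifelse(fs@labels == 1L, 1, -1)
  yD <- ypm * decisionScore(model, X)
  alpha <- rep(0, nrow(X))
  alpha[model@fit$index] <- abs(model@fit$coefs)
  C <- model@cost
  bounded <- alpha >= C - 1e-8
  free <- alpha > 1e-8 & !bounded
  none <- alpha <= 1e-8
  viol <- c(abs(yD[free] - 1), pmax(yD[bounded] - 1, 0),
            pmax(1 - yD[none], 0))
  marginErr <- if (length(model@beta)) {
    abs(model@margin - 1 / sqrt(sum(model@beta^2)))
  } else NA_real_
  list(maxViolation = if (length(viol)) max(viol) else 0,
       marginIdentityError = marginErr, yD = yD)
}
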