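#' @include AllClasses.R AllGenerics.R
NULL

#' Linear discriminant classifier
#'
#' Gaussian linear discriminant analysis for two classes sharing a
#' covariance matrix. A new sample x is assigned to class 1 when
#' \deqn{x' \Sigma^{-1} (\mu_1 - \mu_0) >
#'   \tfrac12 (\mu_1 + \mu_0)' \Sigma^{-1} (\mu_1 - \mu_0)
#'   - \log(P(y=1)/P(y=0)),}
#' with class means, pooled within-class covariance and empirical class
#' proportions estimated from the training set. Boundary ties are assigned
#' to class 0.
#'
#' @slot mu0,mu1 class mean vectors.
#' @slot sigma pooled within-class covariance (after ridge shrinkage).
#' @slot prior0,prior1 empirical class proportions.
#' @slot w discriminant direction `solve(sigma, mu1 - mu0)`.
#' @slot threshold scalar cut-point including the log-prior term.
#' @slot featureNames training feature names.
#' @export
setClass("LDAClassifier",
  representation(mu0 = "numeric", mu1 = "numeric", sigma = "matrix",
                 prior0 = "numeric", prior1 = "numeric", w = "numeric",
                 threshold = "numeric", featureNames = "character")
)

#' Fit the linear discriminant rule
#'
#' Estimates class means, the pooled within-class covariance (unbiased,
#' divisor n - 2) and class priors from a labeled feature set. A ridge term
#' `lambda = ridge * trace(Sigma) / p` is added to the covariance diagonal
#' so that near-singular problems (n close to p, as in whole-session runs
#' with 60 subjects and 24 features) remain solvable.
#'
#' @param fs a \linkS4class{LabeledFeatureSet} containing both classes.
#' @param ridge relative ridge coefficient (default 1e-6).
#' @return an \linkS4class{LDAClassifier}.
#' @seealso [predictClass()], [decisionScore()]
#' @export
fitLDA <- function(fs, ridge = 1e-6) {
  stopifnot(is(fs, "LabeledFeatureSet"))
  X <- fs@features
  y <- fs@labels
  if (length(unique(y)) < 2L) stop("both classes must be present")
  p <- ncol(X)
  if (p < 1L) stop("need at least one feature")
  X0 <- X[y == 0L, , drop = FALSE]
  X1 <- X[y == 1L, , drop = FALSE]
  mu0 <- colMeans(X0)
  mu1 <- colMeans(X1)
  S0 <- crossprod(sweep(X0, 2L, mu0))
  S1 <- crossprod(sweep(X1, 2L, mu1))
  sigma <- (S0 + S1) / (nrow(X) - 2L)
  sigma <- sigma + diag(ridge * sum(diag(sigma)) / p, p)
  w <- solve(sigma, mu1 - mu0)
  prior1 <- nrow(X1) / nrow(X)
  threshold <- 0.5 * sum((mu1 + mu0) * w) - log(prior1 / (1 - prior1))
  new("LDAClassifier", mu0 = mu0, mu1 = mu1, sigma = sigma,
      prior0 = 1 - prior1, prior1 = prior1, w = as.numeric(w),
      threshold = threshold, featureNames = colnames(X))
}

#' @rdname classifier-contract
#' @export
setMethod("decisionScore", "LDAClassifier", function(model, newdata, ...) {
  newdata <- asFeatureMatrix(newdata, model@featureNames)
  as.numeric(newdata %*% model@w) - model@threshold
})

#' @rdname classifier-contract
#' @export
setMethod("predictClass", "LDAClassifier", function(model, newdata, ...) {
  as.integer(decisionScore(model, newdata) > 0)
})

#' Fisher projection of the fitted discriminant
#'
#' Projects samples onto the discriminant direction `a = Sigma^{-1}
#' (mu1 - mu0)`; classification by comparing the projection `z = a'x`
#' against the prior-adjusted cut-point is equivalent to the decision
#' inequality above.
#'
#' @param model an \linkS4class{LDAClassifier}.
#' @param newdata feature matrix.
#' @return numeric vector of projections z.
#' @export
ldaProjection <- function(model, newdata) {
  newdata <- asFeatureMatrix(newdata, model@featureNames)
  as.numeric(newdata %*% model@w)
}

# coerce vectors / data frames and align feature columns
asFeatureMatrix <- function(x, featureNames) {
  if (is(x, "LabeledFeatureSet")) x <- x@features
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && !is.null(featureNames) &&
      all(featureNames %in% colnames(x)))
    x <- x[, featureNames, drop = FALSE]
  if (ncol(x) != length(featureNames))
    stop("feature count mismatch: got ", ncol(x), ", expected ",
         length(featureNames))
  x
}
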