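#' @include AllClasses.R AllGenerics.R classifiers-lda.R
NULL

#' Random forest classifier
#'
#' Ensemble of classification trees grown on bootstrap resamples of the
#' training rows, each split considering only `r` randomly chosen
#' candidate predictors; the ensemble prediction is the majority vote over
#' trees. Defaults follow the study configuration: 1000 trees and
#' `r = round(sqrt(p))` split candidates (5 for the 24-feature inputs).
#'
#' @slot fit the underlying randomForest model.
#' @slot mTrees,r the ensemble size and split-candidate count.
#' @slot featureNames training feature names.
#' @export
setClass("RFClassifier",
  representation(fit = "ANY", mTrees = "integer", r = "integer",
                 featureNames = "character")
)

#' Fit a random forest
#'
#' @param fs a \linkS4class{LabeledFeatureSet} with both classes present.
#' @param mTrees number of trees (default 1000).
#' @param r split candidates per node; default `round(sqrt(p))`.
#' @param seed integer seed; the fit is deterministic given it.
#' @return an \linkS4class{RFClassifier}.
#' @export
fitRF <- function(fs, mTrees = 1000L, r = NULL, seed = 1L) {
  stopifnot(is(fs, "LabeledFeatureSet"))
  X <- fs@features
  y <- fs@labels
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (is.null(r)) r <- as.integer(round(sqrt(ncol(X))))
  if (r < 1L || r > ncol(X)) stop("r must satisfy 1 <= r <= p")
  fit <- withSeed(seed,
    randomForest::randomForest(X, factor(y, levels = c(0L, 1L)),
                               ntree = mTrees, mtry = r))
  new("RFClassifier", fit = fit, mTrees = as.integer(mTrees),
      r = as.integer(r), featureNames = colnames(X))
}

#' @rdname classifier-contract
#' @export
setMethod("predictClass", "RFClassifier", function(model, newdata, ...) {
  newdata <- asFeatureMatrix(newdata, model@featureNames)
  as.integer(as.character(stats::predict(model@fit, newdata)))
})

#' @rdname classifier-contract
#' @export
setMethod("decisionScore", "RFClassifier", function(model, newdata, ...) {
  newdata <- asFeatureMatrix(newdata, model@featureNames)
  pr <- stats::predict(model@fit, newdata, type = "vote", norm.votes = TRUE)
  as.numeric(pr[, "1"]) - 0.5
})

#' Per-tree votes of a fitted forest
#'
#' Exposes the individual tree predictions so the ensemble vote can be
#' checked against a direct tally.
#'
#' @param model an \linkS4class{RFClassifier}.
#' @param newdata feature matrix.
#' @return integer matrix (rows = samples, columns = trees) of 0/1 votes.
#' @export
rfTreeVotes <- function(model, newdata) {
  newdata <- asFeatureMatrix(newdata, model@featureNames)
  ind <- stats::predict(model@fit, newdata, predict.all = TRUE)$individual
  matrix(as.integer(ind == "1"), nrow = nrow(newdata))
}
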