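#' @include AllClasses.R AllGenerics.R classifiers-svm.R features.R
NULL

#' Two-feature linear decision boundary of the group separation
#'
#' Fits a linear support vector machine (cost C = 1) to the per-subject
#' pair (mean global y, mean local y) over ALL subjects at once — no
#' train/test split, no segments — and returns the separating line
#' `beta' x + beta0 = 0`, its margin `M = 1 / ||beta||`, the support
#' subjects and the scatter data. In this plane the two avatar groups
#' separate mainly along the local (height-relative) vertical axis: for a
#' given global hand height, control-group subjects hold their hands
#' higher relative to their own body.
#'
#' @param ds a \linkS4class{MovementDataset} carrying global/local vertical
#'   channels for the requested hand.
#' @param hand hand suffix when channels are per-hand (default right).
#' @param cost SVM cost parameter (default 1).
#' @return a \linkS4class{DecisionBoundary2D}.
#' @examples
#' cfg <- syntheticConfig(nGroup0 = 10, nGroup1 = 10, T = 200, seed = 3)
#' fitBoundary(generateDataset(cfg))
#' @export
fitBoundary <- function(ds, hand = "right", cost = 1) {
  fs <- meanYFeatures(ds, hand)
  if (length(unique(fs@labels)) < 2L)
    stop("boundary requires both groups present")
  model <- fitSVM(fs, kernel = "linear", cost = cost)
  pts <- data.frame(subject_id = fs@subjectIDs,
                    mean_global_y = fs@features[, "mean_global_y"],
                    mean_local_y = fs@features[, "mean_local_y"],
                    group = fs@labels, stringsAsFactors = FALSE)
  new("DecisionBoundary2D", beta = model@beta, beta0 = model@beta0,
      margin = model@margin,
      supportIDs = fs@subjectIDs[model@fit$index], points = pts)
}

#' Export a fitted 2-D boundary as JSON
#'
#' Writes `{beta, beta0, margin, support_ids}` (plus the scatter points)
#' in a machine-readable form.
#'
#' @param boundary a \linkS4class{DecisionBoundary2D}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBoundary <- function(boundary, path) {
  jsonlite::write_json(list(
    beta = as.list(boundary@beta), beta0 = boundary@beta0,
    margin = boundary@margin, support_ids = boundary@supportIDs,
    points = boundary@points), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
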