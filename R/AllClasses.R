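#' @import methods
NULL

#' MovementProfile: one subject's multichannel position time series
#'
#' A `MovementProfile` holds the tracked (or simulated) hand positions of a
#' single subject as a numeric T x C matrix: rows are time points at a fixed
#' sampling rate, columns are positional channels such as the global and
#' local (height-relative) x/y/z coordinates of one or both hands.
#'
#' @slot subjectID character scalar, unique within a dataset.
#' @slot group integer, 0 (age-congruent control avatar) or 1 (old avatar).
#' @slot channels numeric T x C matrix; column names are the channel names.
#' @slot rateHz positive sampling frequency in Hz.
#' @slot height subject height in metres, or `NA_real_` if unknown.
#' @slot handedness `"left"`, `"right"`, or `NA_character_`.
#'
#' @seealso [movementProfile()], [MovementDataset-class]
#' @export
setClass("MovementProfile",
  representation(
    subjectID = "character",
    group = "integer",
    channels = "matrix",
    rateHz = "numeric",
    height = "numeric",
    handedness = "character"
  )
)

setValidity("MovementProfile", function(object) {
  msg <- character()
  if (length(object@subjectID) != 1L || !nzchar(object@subjectID))
    msg <- c(msg, "subjectID must be a non-empty character scalar")
  if (length(object@group) != 1L || !object@group %in% c(0L, 1L))
    msg <- c(msg, "group must be 0 or 1")
  ch <- object@channels
  if (!is.numeric(ch) || nrow(ch) < 1L || ncol(ch) < 1L)
    msg <- c(msg, "channels must be a non-empty numeric matrix")
  if (anyNA(ch) || any(!is.finite(ch)))
    msg <- c(msg, "channels must be finite with no missing values")
  cn <- colnames(ch)
  if (is.null(cn) || anyDuplicated(cn))
    msg <- c(msg, "channels must have unique column names")
  if (length(object@rateHz) != 1L || !is.finite(object@rateHz) ||
      object@rateHz <= 0)
    msg <- c(msg, "rateHz must be a positive number")
  if (length(object@handedness) != 1L ||
      !(is.na(object@handedness) || object@handedness %in% c("left", "right")))
    msg <- c(msg, "handedness must be 'left', 'right' or NA")
  if (length(msg)) msg else TRUE
})

#' MovementDataset: a collection of movement profiles
#'
#' Container for the profiles of one study. All profiles share the same
#' channel names; the number of time points may differ between subjects
#' (as in the variable-duration validation study).
#'
#' @slot profiles list of [MovementProfile-class] objects.
#' @slot metadata free-form named list (provenance, generator settings, ...).
#'
#' @seealso [generateDataset()], [readDataset()]
#' @export
setClass("MovementDataset",
  representation(profiles = "list", metadata = "list")
)

setValidity("MovementDataset", function(object) {
  msg <- character()
  ok <- vapply(object@profiles, is, logical(1), class2 = "MovementProfile")
  if (!all(ok))
    return("all elements of profiles must be MovementProfile objects")
  if (length(object@profiles)) {
    ids <- vapply(object@profiles, function(p) p@subjectID, character(1))
    if (anyDuplicated(ids)) msg <- c(msg, "subject ids must be unique")
    cn <- lapply(object@profiles, function(p) colnames(p@channels))
    if (!all(vapply(cn, identical, logical(1), y = cn[[1]])))
      msg <- c(msg, "all profiles must share the same channel names")
  }
  if (length(msg)) msg else TRUE
})

#' StandardizationParams: pooled per-channel location and scale
#'
#' Mean and standard deviation of each channel pooled over all subjects and
#' all time points of a dataset (population SD convention, i.e. divisor N).
#' With `scope = "global"` a single pooled scalar pair is repeated across
#' channels instead.
#'
#' @slot mean named numeric vector, one entry per channel.
#' @slot sd named numeric vector, strictly positive.
#' @slot scope `"channel"` or `"global"`.
#' @export
setClass("StandardizationParams",
  representation(mean = "numeric", sd = "numeric", scope = "character")
)

setValidity("StandardizationParams", function(object) {
  if (length(object@mean) != length(object@sd))
    return("mean and sd must have equal length")
  if (any(!is.finite(object@sd)) || any(object@sd <= 0))
    return("all sd entries must be positive and finite")
  if (!identical(names(object@mean), names(object@sd)))
    return("mean and sd must carry identical channel names")
  if (!object@scope %in% c("channel", "global"))
    return("scope must be 'channel' or 'global'")
  TRUE
})

#' ChannelPCAModel: per-channel principal components of whole profiles
#'
#' One PCA per channel, fitted on the n x T matrix whose rows are the
#' subjects' trajectories for that channel (observations = subjects,
#' variables = time points). Centering only, no scaling; population
#' variance convention throughout.
#'
#' @slot loadings named list; per channel a T x k orthonormal matrix.
#' @slot centers named list; per channel the length-T training mean trajectory.
#' @slot evr named list; per channel the length-k explained-variance ratios
#'   (non-increasing, summing to at most 1).
#' @slot k integer, components retained per channel.
#' @slot T integer, training profile length.
#' @export
setClass("ChannelPCAModel",
  representation(loadings = "list", centers = "list", evr = "list",
                 k = "integer", T = "integer")
)

setValidity("ChannelPCAModel", function(object) {
  for (ch in names(object@loadings)) {
    L <- object@loadings[[ch]]
    G <- crossprod(L)
    if (max(abs(G - diag(ncol(L)))) > 1e-8)
      return(sprintf("loadings for channel '%s' are not orthonormal", ch))
    e <- object@evr[[ch]]
    if (is.unsorted(rev(e)) || sum(e) > 1 + 1e-8)
      return(sprintf("explained-variance ratios invalid for channel '%s'", ch))
  }
  TRUE
})

#' LabeledFeatureSet: the input contract of the classical classifiers
#'
#' An n x p feature matrix with binary labels and the originating subject id
#' of every row (several rows may share a subject when features are computed
#' on segments).
#'
#' @slot features numeric n x p matrix with column names.
#' @slot labels integer vector in {0,1}, length n.
#' @slot subjectIDs character vector, length n.
#' @export
setClass("LabeledFeatureSet",
  representation(features = "matrix", labels = "integer",
                 subjectIDs = "character")
)

setValidity("LabeledFeatureSet", function(object) {
  n <- nrow(object@features)
  msg <- character()
  if (n < 1L) msg <- c(msg, "feature matrix must have at least one row")
  if (anyNA(object@features) || any(!is.finite(object@features)))
    msg <- c(msg, "features must be finite with no missing values")
  if (is.null(colnames(object@features)))
    msg <- c(msg, "features must have column names")
  if (length(object@labels) != n || !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be a length-n vector in {0,1}")
  if (length(object@subjectIDs) != n)
    msg <- c(msg, "subjectIDs must have length n")
  if (length(msg)) msg else TRUE
})

#' Segment: a contiguous window cut from one profile
#'
#' @slot subjectID originating subject.
#' @slot start 0-based start index; the window covers [start, start + W).
#' @slot data numeric W x C matrix (channel names preserved).
#' @slot group group label inherited from the profile.
#' @export
setClass("Segment",
  representation(subjectID = "character", start = "integer",
                 data = "matrix", group = "integer")
)

setValidity("Segment", function(object) {
  if (object@start < 0L) return("start must be >= 0")
  if (nrow(object@data) < 1L) return("window must contain >= 1 time point")
  TRUE
})

#' EvaluationReport: aggregated results of repeated train/test runs
#'
#' @slot results data.frame with one row per (run, method): run id, per-run
#'   seed, method name, chosen window (NA for whole-session protocols),
#'   correct count and test-set size.
#' @slot votes list of per-run, per-method named prediction vectors.
#' @slot config named list: the resolved configuration snapshot.
#' @export
setClass("EvaluationReport",
  representation(results = "data.frame", votes = "list", config = "list")
)

#' DecisionBoundary2D: a fitted two-feature linear decision boundary
#'
#' The separating line beta' x + beta0 = 0 of a linear support vector
#' machine fitted to two per-subject summary features, with its margin
#' M = 1/||beta|| and the supporting subjects.
#'
#' @slot beta numeric length-2 weight vector (named by feature).
#' @slot beta0 numeric intercept.
#' @slot margin numeric, 1/||beta||.
#' @slot supportIDs character, subject ids of the support vectors.
#' @slot points data.frame of the fitted scatter (subject, features, group).
#' @export
setClass("DecisionBoundary2D",
  representation(beta = "numeric", beta0 = "numeric", margin = "numeric",
                 supportIDs = "character", points = "data.frame")
)

setValidity("DecisionBoundary2D", function(object) {
  if (length(object@beta) != 2L) return("beta must have length 2")
  if (object@margin <= 0) return("margin must be positive")
  TRUE
})
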