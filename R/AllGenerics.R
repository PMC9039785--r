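#' @include AllClasses.R
NULL

#' Accessors for movement data containers
#'
#' @param x a \linkS4class{MovementProfile}, \linkS4class{MovementDataset}
#'   or \linkS4class{LabeledFeatureSet}.
#' @param ... unused.
#' @return `subjectIDs` returns the subject identifier(s); `groupLabels` the
#'   0/1 group labels; `channelMatrix` the T x C numeric matrix of one
#'   profile; `channelNames` the shared channel names; `profiles` the list
#'   of profiles of a dataset; `nSubjects` the number of subjects.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectIDs", function(x, ...) standardGeneric("subjectIDs"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x, ...) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("channelMatrix", function(x, ...) standardGeneric("channelMatrix"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x, ...) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("profiles", function(x, ...) standardGeneric("profiles"))

#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x, ...) standardGeneric("nSubjects"))

#' Classifier prediction contract
#'
#' Every fitted classifier in the package answers `predictClass` (hard 0/1
#' labels) and, where the family exposes one, `decisionScore` (a real-valued
#' score whose sign matches the class; positive = class 1). Scores feed the
#' score-based majority-vote tie-break.
#'
#' @param model a fitted classifier (`LDAClassifier`, `SVMClassifier`,
#'   `RFClassifier`, `FFClassifier`, `CNNClassifier`).
#' @param newdata an n x p feature matrix (or, for the convolutional
#'   network, a list of W x C segment matrices).
#' @param ... unused.
#' @return `predictClass`: integer vector in {0,1}; `decisionScore`: numeric
#'   vector.
#' @name classifier-contract
NULL

#' @rdname classifier-contract
#' @export
setGeneric("predictClass", function(model, newdata, ...)
  standardGeneric("predictClass"))

#' @rdname classifier-contract
#' @export
setGeneric("decisionScore", function(model, newdata, ...)
  standardGeneric("decisionScore"))

# -- accessor methods ---------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("subjectIDs", "MovementProfile", function(x, ...) x@subjectID)

#' @rdname accessors
#' @export
setMethod("subjectIDs", "MovementDataset", function(x, ...)
  vapply(x@profiles, function(p) p@subjectID, character(1)))

#' @rdname accessors
#' @export
setMethod("subjectIDs", "LabeledFeatureSet", function(x, ...) x@subjectIDs)

#' @rdname accessors
#' @export
setMethod("groupLabels", "MovementProfile", function(x, ...) x@group)

#' @rdname accessors
#' @export
setMethod("groupLabels", "MovementDataset", function(x, ...)
  vapply(x@profiles, function(p) p@group, integer(1)))

#' @rdname accessors
#' @export
setMethod("groupLabels", "LabeledFeatureSet", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("channelMatrix", "MovementProfile", function(x, ...) x@channels)

#' @rdname accessors
#' @export
setMethod("channelNames", "MovementProfile", function(x, ...)
  colnames(x@channels))

#' @rdname accessors
#' @export
setMethod("channelNames", "MovementDataset", function(x, ...) {
  if (!length(x@profiles)) return(character())
  colnames(x@profiles[[1]]@channels)
})

#' @rdname accessors
#' @export
setMethod("profiles", "MovementDataset", function(x, ...) x@profiles)

#' @rdname accessors
#' @export
setMethod("nSubjects", "MovementDataset", function(x, ...)
  length(x@profiles))

#' @describeIn accessors number of profiles in a dataset.
#' @export
setMethod("length", "MovementDataset", function(x) length(x@profiles))

#' Extract single profiles or subset a dataset
#'
#' @param x a MovementDataset.
#' @param i numeric/logical index or subject id(s).
#' @param j,...,drop unused.
#' @return `[[` returns one \linkS4class{MovementProfile}; `[` a subsetted
#'   \linkS4class{MovementDataset}.
#' @name dataset-subset
NULL

#' @rdname dataset-subset
#' @export
setMethod("[[", "MovementDataset", function(x, i, j, ...) {
  if (is.character(i)) i <- match(i, subjectIDs(x))
  x@profiles[[i]]
})

#' @rdname dataset-subset
#' @export
setMethod("[", "MovementDataset", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, subjectIDs(x))
  new("MovementDataset", profiles = x@profiles[i], metadata = x@metadata)
})

# -- show methods -------------------------------------------------------------

setMethod("show", "MovementProfile", function(object) {
  cat(sprintf(
    "MovementProfile '%s' (group %d): %d time points x %d channels @ %g Hz\n",
    object@subjectID, object@group, nrow(object@channels),
    ncol(object@channels), object@rateHz))
})

setMethod("show", "MovementDataset", function(object) {
  n <- length(object@profiles)
  cat(sprintf("MovementDataset: %d profiles\n", n))
  if (n) {
    g <- groupLabels(object)
    Ts <- vapply(object@profiles, function(p) nrow(p@channels), integer(1))
    cat(sprintf("  groups: %d x 0, %d x 1\n", sum(g == 0L), sum(g == 1L)))
    cat(sprintf("  channels (%d): %s\n", length(channelNames(object)),
                paste(channelNames(object), collapse = ", ")))
    cat(sprintf("  time points: %s\n",
                if (length(unique(Ts)) == 1L) as.character(Ts[1])
                else sprintf("%d-%d", min(Ts), max(Ts))))
  }
})

setMethod("show", "StandardizationParams", function(object) {
  cat(sprintf("StandardizationParams (%s scope) for %d channels\n",
              object@scope, length(object@mean)))
})

setMethod("show", "LabeledFeatureSet", function(object) {
  cat(sprintf("LabeledFeatureSet: %d rows x %d features (%d | %d labels)\n",
              nrow(object@features), ncol(object@features),
              sum(object@labels == 0L), sum(object@labels == 1L)))
})

setMethod("show", "ChannelPCAModel", function(object) {
  cat(sprintf("ChannelPCAModel: %d channels x %d components (T = %d)\n",
              length(object@loadings), object@k, object@T))
})

setMethod("show", "EvaluationReport", function(object) {
  res <- object@results
  cat(sprintf("EvaluationReport: %d runs x %d method(s)\n",
              length(unique(res$run)), length(unique(res$method))))
  for (m in unique(res$method)) {
    r <- res[res$method == m, ]
    cat(sprintf("  %-8s mean correct %.2f / %d\n", m, mean(r$correct),
                r$nTest[1]))
  }
})

setMethod("show", "DecisionBoundary2D", function(object) {
  cat(sprintf(
    "DecisionBoundary2D: %.4f * %s + %.4f * %s + %.4f = 0 (margin %.4f)\n",
    object@beta[1], names(object@beta)[1], object@beta[2],
    names(object@beta)[2], object@beta0, object@margin))
})
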