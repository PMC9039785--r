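#' @include AllClasses.R AllGenerics.R
NULL

#' Randomly sample fixed-length segments from every subject
#'
#' Window slicing: for each subject, `mPerSubject` start indices are drawn
#' uniformly and independently (with replacement) from `{0, ..., T - W}`,
#' so segments may overlap or repeat within a subject; every call with a
#' fresh seed draws completely new segments. Windows are half-open
#' `[start, start + W)` in time-point units — never seconds — so the same
#' W spans different durations at different sampling rates.
#'
#' @param ds a \linkS4class{MovementDataset}; every profile needs `T >= W`.
#' @param W window length in time points.
#' @param mPerSubject segments per subject.
#' @param seed integer seed for the draw.
#' @return list of \linkS4class{Segment} objects
#'   (`length(ds) * mPerSubject` of them, grouped by subject).
#' @examples
#' cfg <- syntheticConfig(nGroup0 = 2, nGroup1 = 2, T = 60, seed = 1)
#' segs <- sampleSegments(generateDataset(cfg), W = 20, mPerSubject = 3,
#'                        seed = 7)
#' length(segs)
#' @export
sampleSegments <- function(ds, W, mPerSubject, seed) {
  stopifnot(is(ds, "MovementDataset"), W >= 1L, mPerSubject >= 1L)
  W <- as.integer(W)
  withSeed(seed, {
    out <- vector("list", length(ds) * mPerSubject)
    k <- 0L
    for (p in profiles(ds)) {
      T <- nrow(p@channels)
      if (T < W)
        stop(sprintf("subject '%s' has only %d time points (< W = %d)",
                     p@subjectID, T, W))
      starts <- sample.int(T - W + 1L, mPerSubject, replace = TRUE) - 1L
      for (s in starts) {
        k <- k + 1L
        out[[k]] <- new("Segment", subjectID = p@subjectID,
                        start = s,
                        data = p@channels[(s + 1L):(s + W), , drop = FALSE],
                        group = p@group)
      }
    }
    out
  })
}

#' Serialize a segment plan for audit
#'
#' @param segments list of \linkS4class{Segment}s.
#' @return data.frame with subject id, 0-based start, window length and
#'   group label, one row per segment.
#' @export
segmentPlan <- function(segments) {
  data.frame(
    subject_id = vapply(segments, function(s) s@subjectID, character(1)),
    start = vapply(segments, function(s) s@start, integer(1)),
    W = vapply(segments, function(s) nrow(s@data), integer(1)),
    group = vapply(segments, function(s) s@group, integer(1)),
    stringsAsFactors = FALSE)
}

#' Basic-feature representation of a list of segments
#'
#' @param segments list of \linkS4class{Segment}s.
#' @return a \linkS4class{LabeledFeatureSet} with one row per segment
#'   (subject ids repeat across a subject's segments).
#' @export
segmentFeatureSet <- function(segments) {
  if (!length(segments)) stop("no segments")
  feats <- t(vapply(segments, function(s) basicFeatures(s@data),
                    numeric(4L * ncol(segments[[1]]@data))))
  new("LabeledFeatureSet",
      features = feats,
      labels = vapply(segments, function(s) s@group, integer(1)),
      subjectIDs = vapply(segments, function(s) s@subjectID, character(1)))
}

#' Per-subject majority vote over segment predictions
#'
#' Aggregates hard 0/1 segment predictions into one label per subject by
#' taking the modal class. Exact ties (possible because the number of
#' segments per subject is even) are resolved by the sign of the subject's
#' mean real-valued decision score when `scores` are supplied, and by a
#' seeded fair coin otherwise.
#'
#' @param predictions integer vector of 0/1 segment predictions.
#' @param subjects character vector, same length: originating subject ids.
#' @param scores optional numeric decision scores (positive = class 1) used
#'   for tie-breaking.
#' @param seed seed for the coin-flip fallback.
#' @return named integer vector of 0/1 labels, one per distinct subject (in
#'   order of first appearance).
#' @export
majorityVote <- function(predictions, subjects, scores = NULL, seed = 1L) {
  stopifnot(length(predictions) == length(subjects))
  if (!length(predictions)) stop("empty prediction list")
  if (!all(predictions %in% c(0L, 1L))) stop("predictions must be 0/1")
  ids <- unique(subjects)
  coinSeeds <- spawnSeeds(seed, length(ids))
  out <- setNames(integer(length(ids)), ids)
  for (i in seq_along(ids)) {
    sel <- subjects == ids[i]
    n1 <- sum(predictions[sel] == 1L)
    n0 <- sum(sel) - n1
    out[i] <- if (n1 > n0) 1L else if (n1 < n0) 0L else if
    (!is.null(scores)) {
      ms <- mean(scores[sel])
      if (ms > 0) 1L else if (ms < 0) 0L else
        withSeed(coinSeeds[i], sample(0:1, 1L))
    } else withSeed(coinSeeds[i], sample(0:1, 1L))
  }
  out
}
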