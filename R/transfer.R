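#' @include AllClasses.R AllGenerics.R protocols.R
NULL

#' Cross-study transfer classification
#'
#' Trains on every subject of one study and predicts every subject of an
#' independent second study, with no train/test split: the subject sets
#' stay fixed and run-to-run variation comes only from the random segment
#' draws. The window length is fixed in time points (default 200) and is
#' deliberately NOT rescaled between sampling rates — 200 points mean 20 s
#' at 10 Hz but 200 s at 1 Hz. Training uses the right-hand channels;
#' each test subject contributes the hand matching their handedness.
#' Standardization is fitted separately on each dataset.
#'
#' @param trainDs training \linkS4class{MovementDataset} (equal or unequal
#'   lengths; per-hand channel names, or already reduced to one hand).
#' @param testDs validation \linkS4class{MovementDataset}; every profile
#'   must be at least `W` long.
#' @param W fixed window length in time points (default 200).
#' @param mPerSubject segments per subject and side (default 30).
#' @param methods classifier families (default SVM_LIN).
#' @param nRuns repetitions (the study uses 100).
#' @param seed master seed.
#' @return an \linkS4class{EvaluationReport}; `correct` counts are out of
#'   the number of validation subjects.
#' @export
transferRun <- function(trainDs, testDs, W = 200L, mPerSubject = 30L,
                        methods = "SVM_LIN", nRuns = 100L, seed = 1L) {
  stopifnot(is(trainDs, "MovementDataset"), is(testDs, "MovementDataset"))
  bad <- setdiff(methods, .allMethods)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  # handedness-aware channel filter, before standardization
  if (!all(c("global_y", "local_y") %in% channelNames(trainDs)))
    trainDs <- selectHandChannels(trainDs, "right")
  if (!all(c("global_y", "local_y") %in% channelNames(testDs)))
    testDs <- selectHandChannels(testDs, "by_handedness")
  if (!identical(channelNames(trainDs), channelNames(testDs)))
    stop("channel-name mismatch between training and test datasets")
  shortT <- vapply(profiles(testDs), function(p) nrow(p@channels),
                   integer(1)) < W
  if (any(shortT))
    stop("test subject(s) shorter than W: ",
         paste(subjectIDs(testDs)[shortT], collapse = ", "))
  needFeat <- any(methods %in% .classicalMethods)
  needRaw <- "CNN" %in% methods
  truth <- setNames(groupLabels(testDs), subjectIDs(testDs))
  runSeeds <- spawnSeeds(seed, nRuns)
  rows <- list(); votes <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    rs <- spawnSeeds(runSeeds[r], 3L)
    tr <- segmentSide(trainDs, subjectIDs(trainDs), W, mPerSubject,
                      rs[1], needFeat, needRaw)
    te <- segmentSide(testDs, subjectIDs(testDs), W, mPerSubject,
                      rs[2], needFeat, needRaw)
    runVotes <- list()
    for (m in methods) {
      model <- fitMethod(m, tr$fs, seed = rs[3], segments = tr$segments)
      v <- voteSubjects(model, te$fs, te$segsAll, seed = rs[3])
      runVotes[[m]] <- v
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, seed = runSeeds[r], method = m, window = as.integer(W),
        correct = sum(v == truth[names(v)]), nTest = length(truth))
    }
    votes[[r]] <- runVotes
  }
  newReport(rows, votes, list(
    protocol = "transfer", W = W, mPerSubject = mPerSubject,
    methods = methods, nRuns = nRuns, seed = seed, runSeeds = runSeeds))
}
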