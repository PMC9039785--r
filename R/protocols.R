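#' @include AllClasses.R AllGenerics.R segments.R features.R
NULL

.classicalMethods <- c("LDA", "FF", "RF", "SVM_RBF", "SVM_LIN")
.allMethods <- c(.classicalMethods, "CNN")

#' Draw a balanced train/test split of subjects
#'
#' Samples exactly `nTestPerClass` subjects per class uniformly at random
#' into the test set; all remaining subjects train.
#'
#' @param ds a \linkS4class{MovementDataset}.
#' @param nTestPerClass test subjects per class (default 6).
#' @param seed integer seed.
#' @return list with character vectors `train` and `test` (class
#'   `"SplitPlan"`).
#' @export
makeSplit <- function(ds, nTestPerClass = 6L, seed = 1L) {
  stopifnot(is(ds, "MovementDataset"))
  ids <- subjectIDs(ds)
  g <- groupLabels(ds)
  for (k in 0:1) {
    if (sum(g == k) < nTestPerClass)
      stop(sprintf("class %d has only %d subjects (< %d test)",
                   k, sum(g == k), nTestPerClass))
  }
  test <- withSeed(seed, c(
    if (nTestPerClass > 0L) sample(ids[g == 0L], nTestPerClass),
    if (nTestPerClass > 0L) sample(ids[g == 1L], nTestPerClass)))
  structure(list(train = setdiff(ids, test), test = as.character(test)),
            class = "SplitPlan")
}

# fit one classifier family on a feature set (or, for CNN, raw segments)
fitMethod <- function(method, fs, seed, segments = NULL) {
  switch(method,
    LDA = fitLDA(fs),
    SVM_LIN = fitSVM(fs, kernel = "linear"),
    SVM_RBF = fitSVM(fs, kernel = "radial"),
    RF = fitRF(fs, seed = seed),
    FF = fitFF(fs, seed = seed),
    CNN = fitCNN(segments, seed = seed),
    stop("unknown method: ", method))
}

# per-subject majority-vote predictions of one fitted model over segments
voteSubjects <- function(model, fs = NULL, segments = NULL, seed = 1L) {
  if (is(model, "CNNClassifier")) {
    pred <- predictClass(model, segments)
    score <- decisionScore(model, segments)
    subj <- vapply(segments, function(s) s@subjectID, character(1))
  } else {
    pred <- predictClass(model, fs@features)
    score <- decisionScore(model, fs@features)
    subj <- fs@subjectIDs
  }
  majorityVote(pred, subj, scores = score, seed = seed)
}

newReport <- function(rows, votes, config) {
  new("EvaluationReport", results = do.call(rbind, rows), votes = votes,
      config = config)
}

#' Repeated whole-session classification
#'
#' The whole-session protocol: in each of `nRuns` repetitions a balanced
#' test set is drawn, training and test profiles are standardized
#' separately, whole-profile features are extracted (per-channel PCA scores
#' fitted on the unstandardized training profiles only, or basic summary
#' features of the standardized profiles), each classical classifier is
#' fitted on the training feature vectors, and the number of correctly
#' classified test subjects is recorded.
#'
#' @param ds a \linkS4class{MovementDataset} of equal-length profiles.
#' @param featureMode `"pca"` (k components per channel) or `"basic"`.
#' @param methods subset of LDA, FF, RF, SVM_RBF, SVM_LIN.
#' @param nRuns repetitions (the study uses 100).
#' @param nTestPerClass test subjects per class (default 6).
#' @param pcaK PCA components per channel (default 4).
#' @param seed master seed; per-run seeds are spawned from it and logged.
#' @return an \linkS4class{EvaluationReport}.
#' @export
runWholeSession <- function(ds, featureMode = c("pca", "basic"),
                            methods = .classicalMethods, nRuns = 100L,
                            nTestPerClass = 6L, pcaK = 4L, seed = 1L) {
  featureMode <- match.arg(featureMode)
  stopifnot(is(ds, "MovementDataset"))
  bad <- setdiff(methods, .classicalMethods)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  Ts <- vapply(profiles(ds), function(p) nrow(p@channels), integer(1))
  if (length(unique(Ts)) != 1L)
    stop("whole-session protocol requires equal profile lengths")
  runSeeds <- spawnSeeds(seed, nRuns)
  rows <- list(); votes <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    rs <- spawnSeeds(runSeeds[r], 4L)
    split <- makeSplit(ds, nTestPerClass, seed = rs[1])
    trainDs <- ds[split$train]
    testDs <- ds[split$test]
    if (featureMode == "pca") {
      pca <- fitChannelPCA(trainDs, k = pcaK)
      trainFS <- projectPCA(pca, trainDs)
      testFS <- projectPCA(pca, testDs)
    } else {
      trainFS <- basicFeatureSet(
        applyStandardizer(trainDs, fitStandardizer(trainDs)))
      testFS <- basicFeatureSet(
        applyStandardizer(testDs, fitStandardizer(testDs)))
    }
    truth <- setNames(groupLabels(testDs), subjectIDs(testDs))
    runVotes <- list()
    for (m in methods) {
      model <- fitMethod(m, trainFS, seed = rs[2])
      pred <- setNames(predictClass(model, testFS@features),
                       testFS@subjectIDs)
      runVotes[[m]] <- pred
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, seed = runSeeds[r], method = m, window = NA_integer_,
        correct = sum(pred == truth[names(pred)]), nTest = length(truth))
    }
    votes[[r]] <- runVotes
  }
  newReport(rows, votes, list(
    protocol = "whole_session", featureMode = featureMode,
    methods = methods, nRuns = nRuns, nTestPerClass = nTestPerClass,
    pcaK = pcaK, seed = seed, runSeeds = runSeeds))
}

# stratified subject-level fold assignment (balanced classes per fold)
assignFolds <- function(ids, groups, nFolds, seed) {
  fold <- setNames(integer(length(ids)), ids)
  withSeed(seed, {
    for (k in 0:1) {
      sel <- sample(ids[groups == k])
      fold[sel] <- rep_len(seq_len(nFolds), length(sel))
    }
  })
  fold
}

# segment draw + features for a subject subset, standardized on itself;
# with raw segments requested both representations share one segment draw
segmentSide <- function(ds, ids, W, m, seed, needFeatures, needRaw) {
  sub <- ds[ids]
  std <- applyStandardizer(sub, fitStandardizer(sub))
  if (needRaw) {
    segs <- sampleSegments(std, W, m, seed)
    list(segments = segs,
         fs = if (needFeatures) segmentFeatureSet(segs) else NULL,
         truth = setNames(groupLabels(sub), subjectIDs(sub)),
         segsAll = segs)
  } else {
    list(segments = NULL,
         fs = fastSegmentFeatures(std, W, m, seed),
         truth = setNames(groupLabels(sub), subjectIDs(sub)),
         segsAll = NULL)
  }
}

#' Repeated segmental classification with inner window selection
#'
#' The window-slicing protocol: in each run a balanced test split is drawn;
#' an inner subject-level cross-validation over the candidate window grid
#' picks, per classifier, the window length maximising majority-vote
#' accuracy (ties go to the smallest window); the final model is trained on
#' `mPerSubject` fresh random segments from every training subject at the
#' chosen window and evaluated by majority vote over the test subjects'
#' segments. Training and test sides (and the inner folds) are always
#' standardized separately. Classical classifiers consume the four basic
#' features per channel of each segment; the convolutional network consumes
#' the raw standardized segments.
#'
#' @param ds a \linkS4class{MovementDataset}; every profile must be at
#'   least `max(windowGrid)` long.
#' @param windowGrid candidate window lengths in time points
#'   (default `c(50, 200, 350, 500, 650)`).
#' @param mPerSubject segments per subject (default 30).
#' @param methods subset of LDA, FF, RF, SVM_RBF, SVM_LIN, CNN.
#' @param innerFolds inner cross-validation folds (default 5).
#' @param nRuns repetitions (the study uses 100).
#' @param nTestPerClass test subjects per class (default 6).
#' @param seed master seed.
#' @return an \linkS4class{EvaluationReport}; the `window` column records
#'   each run's chosen length per method.
#' @export
runSegmental <- function(ds, windowGrid = c(50L, 200L, 350L, 500L, 650L),
                         mPerSubject = 30L, methods = .allMethods,
                         innerFolds = 5L, nRuns = 100L,
                         nTestPerClass = 6L, seed = 1L) {
  stopifnot(is(ds, "MovementDataset"))
  bad <- setdiff(methods, .allMethods)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  Ts <- vapply(profiles(ds), function(p) nrow(p@channels), integer(1))
  short <- Ts < max(windowGrid)
  if (any(short))
    stop("subject(s) shorter than max window: ",
         paste(subjectIDs(ds)[short], collapse = ", "))
  needFeat <- any(methods %in% .classicalMethods)
  needRaw <- "CNN" %in% methods
  runSeeds <- spawnSeeds(seed, nRuns)
  rows <- list(); votes <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    rs <- spawnSeeds(runSeeds[r], 6L)
    split <- makeSplit(ds, nTestPerClass, seed = rs[1])
    trainDs <- ds[split$train]
    chosenW <- setNames(rep(windowGrid[1], length(methods)), methods)
    if (length(windowGrid) > 1L) {
      fold <- assignFolds(subjectIDs(trainDs), groupLabels(trainDs),
                          innerFolds, seed = rs[2])
      cvAcc <- matrix(0, length(methods), length(windowGrid),
                      dimnames = list(methods, NULL))
      cvN <- rep(0L, length(windowGrid))
      foldSeeds <- spawnSeeds(rs[3], innerFolds * length(windowGrid) * 2L)
      fi <- 0L
      for (wi in seq_along(windowGrid)) {
        W <- windowGrid[wi]
        for (f in seq_len(innerFolds)) {
          fi <- fi + 1L
          inTrain <- names(fold)[fold != f]
          inTest <- names(fold)[fold == f]
          # degenerate folds (possible for very small datasets) are skipped
          gTr <- groupLabels(trainDs)[match(inTrain, subjectIDs(trainDs))]
          if (!length(inTest) || length(unique(gTr)) < 2L) next
          tr <- segmentSide(trainDs, inTrain, W, mPerSubject,
                            foldSeeds[2L * fi - 1L], needFeat, needRaw)
          te <- segmentSide(trainDs, inTest, W, mPerSubject,
                            foldSeeds[2L * fi], needFeat, needRaw)
          cvN[wi] <- cvN[wi] + 1L
          for (m in methods) {
            model <- fitMethod(m, tr$fs, seed = foldSeeds[2L * fi],
                               segments = tr$segments)
            v <- voteSubjects(model, te$fs, te$segsAll,
                              seed = foldSeeds[2L * fi])
            cvAcc[m, wi] <- cvAcc[m, wi] + mean(v == te$truth[names(v)])
          }
        }
      }
      cvAcc <- sweep(cvAcc, 2L, pmax(cvN, 1L), "/")
      for (m in methods)
        chosenW[m] <- windowGrid[which.max(cvAcc[m, ])]  # first max = smallest W
    }
    # final fit at each method's chosen window; segment draws shared per W
    testDs <- ds[split$test]
    truth <- setNames(groupLabels(testDs), subjectIDs(testDs))
    sideCache <- list()
    getSides <- function(W) {
      key <- as.character(W)
      if (is.null(sideCache[[key]])) {
        sTr <- as.integer((as.numeric(rs[4]) + W) %% 2147483647)
        sTe <- as.integer((as.numeric(rs[5]) + W) %% 2147483647)
        sideCache[[key]] <<- list(
          tr = segmentSide(trainDs, subjectIDs(trainDs), W, mPerSubject,
                           sTr, needFeat, needRaw),
          te = segmentSide(testDs, subjectIDs(testDs), W, mPerSubject,
                           sTe, needFeat, needRaw))
      }
      sideCache[[key]]
    }
    runVotes <- list()
    for (m in methods) {
      sides <- getSides(chosenW[m])
      model <- fitMethod(m, sides$tr$fs, seed = rs[6],
                         segments = sides$tr$segments)
      v <- voteSubjects(model, sides$te$fs, sides$te$segsAll, seed = rs[6])
      runVotes[[m]] <- v
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, seed = runSeeds[r], method = m,
        window = as.integer(chosenW[m]),
        correct = sum(v == truth[names(v)]), nTest = length(truth))
    }
    votes[[r]] <- runVotes
  }
  newReport(rows, votes, list(
    protocol = "segmental", windowGrid = windowGrid,
    mPerSubject = mPerSubject, methods = methods, innerFolds = innerFolds,
    nRuns = nRuns, nTestPerClass = nTestPerClass, seed = seed,
    runSeeds = runSeeds))
}

#' Segmental classification on the two vertical-position channels only
#'
#' The reduced-input ablation: identical to [runSegmental()] but with the
#' dataset restricted to the global and local vertical (y) channels of one
#' hand (2 channels x 4 basic features = 8 features per segment).
#'
#' @param ds a \linkS4class{MovementDataset} with per-hand channel names.
#' @param hand which hand's channels to keep (default right).
#' @param methods classifier families (default SVM_LIN).
#' @param ... passed on to [runSegmental()].
#' @return an \linkS4class{EvaluationReport}.
#' @export
runReducedInput <- function(ds, hand = "right", methods = "SVM_LIN", ...) {
  cn <- channelNames(ds)
  want <- if (all(c("global_y", "local_y") %in% cn)) {
    c("global_y", "local_y")
  } else paste(c("global_y", "local_y"), hand, sep = "_")
  runSegmental(selectChannels(ds, want), methods = methods, ...)
}

#' Histogram of correct-classification counts
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param method classifier family to tabulate (default: all pooled).
#' @return named integer table over 0..nTest correct counts.
#' @export
correctHistogram <- function(report, method = NULL) {
  res <- report@results
  if (!is.null(method)) res <- res[res$method == method, ]
  table(factor(res$correct, levels = 0:max(res$nTest)))
}
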