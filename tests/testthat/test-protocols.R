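test_that("balanced splits reproduce the study's training composition", {
  ds <- generateDataset(syntheticConfig(nGroup0 = 35, nGroup1 = 37, T = 30,
                                        seed = 2))
  split <- makeSplit(ds, nTestPerClass = 6, seed = 1)
  g <- setNames(groupLabels(ds), subjectIDs(ds))
  # 35/37 subjects minus 6+6 test -> 29 and 31 training patterns
  expect_equal(sum(g[split$train] == 0L), 29L)
  expect_equal(sum(g[split$train] == 1L), 31L)
  expect_equal(sum(g[split$test] == 0L), 6L)
  expect_equal(sum(g[split$test] == 1L), 6L)
})

test_that("splits stay disjoint and balanced across many seeds and handle
           edge cases", {
  ds <- tinyDataset(n0 = 8, n1 = 9, T = 20, seed = 3)
  g <- setNames(groupLabels(ds), subjectIDs(ds))
  for (s in 1:200) {
    sp <- makeSplit(ds, nTestPerClass = 3, seed = s)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_equal(unname(table(g[sp$test])), c(3L, 3L), ignore_attr = TRUE)
    expect_setequal(c(sp$train, sp$test), subjectIDs(ds))
  }
  all_train <- makeSplit(ds, nTestPerClass = 0, seed = 1)
  expect_length(all_train$test, 0L)
  expect_setequal(all_train$train, subjectIDs(ds))
  expect_error(makeSplit(ds, nTestPerClass = 9, seed = 1), "class 0")
})

test_that("whole-session evaluation books every run for every method and
           separates leakage paths", {
  ds <- tinyDataset(n0 = 8, n1 = 8, T = 60, delta = 3, seed = 6)
  rep <- runWholeSession(ds, featureMode = "pca",
                         methods = c("LDA", "SVM_LIN"), nRuns = 4,
                         nTestPerClass = 3, pcaK = 2, seed = 11)
  res <- rep@results
  expect_equal(nrow(res), 8L)  # 4 runs x 2 methods
  expect_true(all(table(res$method) == 4L))
  expect_true(all(res$nTest == 6L))
  expect_true(all(res$correct >= 0 & res$correct <= 6))
  expect_true(all(is.na(res$window)))
  # votes carry exactly the test subjects of each run, disjoint from train
  for (r in seq_len(4)) {
    ids <- names(rep@votes[[r]][["SVM_LIN"]])
    expect_length(ids, 6L)
    expect_true(all(ids %in% subjectIDs(ds)))
  }
  # identical seeds reproduce the full report
  rep2 <- runWholeSession(ds, featureMode = "pca",
                          methods = c("LDA", "SVM_LIN"), nRuns = 4,
                          nTestPerClass = 3, pcaK = 2, seed = 11)
  expect_identical(rep@results, rep2@results)
})

test_that("a strong planted separation saturates whole-session linear
           classifiers", {
  ds <- tinyDataset(n0 = 10, n1 = 10, T = 150, delta = 4, seed = 7)
  rep <- runWholeSession(ds, featureMode = "basic", methods = "SVM_LIN",
                         nRuns = 5, nTestPerClass = 3, seed = 13)
  expect_gte(mean(rep@results$correct), 5.5)
})

test_that("whole-session evaluation rejects unequal lengths and unknown
           methods", {
  ds2 <- generateDataset(syntheticConfig(nGroup0 = 4, nGroup1 = 4,
                                         T = c(40L, 60L), seed = 2),
                         "study2")
  expect_error(runWholeSession(ds2, "basic", methods = "LDA", nRuns = 1),
               "equal profile lengths")
  ds <- tinyDataset(n0 = 4, n1 = 4, T = 30, seed = 2)
  expect_error(runWholeSession(ds, "basic", methods = "QDA", nRuns = 1),
               "unknown method")
  expect_error(runSegmental(ds, windowGrid = 50L, methods = "XX",
                            nRuns = 1), "unknown method")
})

test_that("segmental evaluation selects windows from the grid and a
           singleton grid short-circuits the inner CV", {
  ds <- tinyDataset(n0 = 6, n1 = 6, T = 90, delta = 2, seed = 9)
  rep <- runSegmental(ds, windowGrid = c(20L, 40L), mPerSubject = 6,
                      methods = c("LDA", "SVM_LIN"), innerFolds = 2,
                      nRuns = 3, nTestPerClass = 2, seed = 15)
  expect_true(all(rep@results$window %in% c(20L, 40L)))
  expect_equal(nrow(rep@results), 6L)
  expect_true(all(rep@results$nTest == 4L))
  one <- runSegmental(ds, windowGrid = 25L, mPerSubject = 4,
                      methods = "SVM_LIN", nRuns = 2, nTestPerClass = 2,
                      seed = 3)
  expect_true(all(one@results$window == 25L))
})

test_that("segmental runs error when any subject is shorter than the
           largest window", {
  ds <- madeDataset(
    madeProfile("long", 0, cbind(local_y_right = rnorm(100))),
    madeProfile("short", 1, cbind(local_y_right = rnorm(30))))
  expect_error(runSegmental(ds, windowGrid = c(20L, 50L), nRuns = 1,
                            methods = "LDA", nTestPerClass = 0),
               "short")
})

test_that("the reduced vertical-channel input keeps the protocol schema
           with 8 features", {
  ds <- tinyDataset(n0 = 5, n1 = 5, T = 80, delta = 2, seed = 10)
  reduced <- selectChannels(ds, c("global_y_right", "local_y_right"))
  expect_length(channelNames(reduced), 2L)
  fs <- segmentFeatureSet(sampleSegments(reduced, 20, 2, seed = 1))
  expect_equal(ncol(fs@features), 8L)  # 2 channels x 4 basic features
  rep <- runReducedInput(ds, windowGrid = c(20L, 40L), mPerSubject = 5,
                         innerFolds = 2, nRuns = 2, nTestPerClass = 2,
                         seed = 4)
  expect_identical(unique(rep@results$method), "SVM_LIN")
  expect_identical(names(rep@results),
                   c("run", "seed", "method", "window", "correct", "nTest"))
})

test_that("the segmental protocol also carries the convolutional network
           end to end", {
  ds <- tinyDataset(n0 = 4, n1 = 4, T = 120, delta = 3, seed = 12)
  rep <- runSegmental(ds, windowGrid = 50L, mPerSubject = 4,
                      methods = c("SVM_LIN", "CNN"), nRuns = 1,
                      nTestPerClass = 2, seed = 21)
  expect_setequal(unique(rep@results$method), c("SVM_LIN", "CNN"))
  expect_true(all(rep@results$correct >= 0 & rep@results$correct <= 4))
})

test_that("correct-count histograms tabulate the report", {
  ds <- tinyDataset(n0 = 5, n1 = 5, T = 60, delta = 2, seed = 2)
  rep <- runWholeSession(ds, "basic", methods = "LDA", nRuns = 3,
                         nTestPerClass = 2, seed = 5)
  h <- correctHistogram(rep, "LDA")
  expect_equal(sum(h), 3L)
  expect_length(h, 5L)  # counts 0..4
})
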