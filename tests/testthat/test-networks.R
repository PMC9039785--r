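test_that("softmax output is uniform for zero logits and always
           normalized", {
  # an untrained zero-initialised network outputs (0.5, 0.5) everywhere
  fs <- randomFeatureSet(n = 10, p = 3, seed = 1)
  net0 <- fitFF(fs, epochs = 0L, initSD = 0, seed = 1)
  pr <- ffProbabilities(net0, fs@features)
  expect_true(all(pr == 0.5))
  # trained probabilities still sum to one row-wise
  net <- fitFF(fs, epochs = 3L, seed = 2)
  pr2 <- ffProbabilities(net, fs@features)
  expect_equal(rowSums(pr2), rep(1, 10), tolerance = 1e-12)
  expect_true(all(pr2 >= 0))
})

test_that("the feedforward network learns linearly separable features
           within 10 epochs", {
  fs <- randomFeatureSet(n = 60, p = 2, sep = 4, seed = 12)
  net <- fitFF(fs, seed = 3)
  expect_equal(mean(predictClass(net, fs@features) == fs@labels), 1)
})

test_that("feedforward fits are reproducible under a fixed seed", {
  fs <- randomFeatureSet(n = 30, p = 3, sep = 1, seed = 9)
  n1 <- fitFF(fs, seed = 7)
  n2 <- fitFF(fs, seed = 7)
  expect_identical(n1@params, n2@params)
  sc1 <- decisionScore(n1, fs@features)
  expect_true(all(sign(sc1) == sign(2 * predictClass(n1, fs@features) - 1) |
                    sc1 == 0))
})

test_that("valid cross-correlation matches the printed formula on the
           worked example and a brute-force oracle", {
  # an 8-point segment with a length-3 kernel slides over 8 - 3 + 1 = 6 steps
  S <- matrix(rnorm(8 * 6), 8, 6)
  K <- matrix(rnorm(3 * 6), 3, 6)
  expect_length(conv1dValid(S, K), 6L)
  # all-zero kernel leaves only the bias
  expect_equal(conv1dValid(S, K * 0, bias = 0.7), rep(0.7, 6))
  bruteConv <- function(S, K) {
    W <- nrow(S); F <- nrow(K); C <- ncol(S)
    out <- numeric(W - F + 1)
    for (i in seq_len(W - F + 1)) {
      acc <- 0
      for (c in seq_len(C)) for (u in seq_len(F)) {
        acc <- acc + K[u, c] * S[i + u - 1, c]
      }
      out[i] <- acc
    }
    out
  }
  withr::with_seed(14, {
    for (i in 1:25) {
      W <- sample(3:20, 1); F <- sample(seq_len(W), 1)
      C <- sample(1:4, 1)
      S <- matrix(rnorm(W * C), W, C)
      K <- matrix(rnorm(F * C), F, C)
      expect_equal(conv1dValid(S, K), bruteConv(S, K), tolerance = 1e-12)
    }
  })
  expect_error(conv1dValid(matrix(0, 2, 1), matrix(0, 3, 1)), "exceeds")
})

test_that("max pooling matches its loop oracle and boundary cases", {
  expect_equal(maxPool1d(1:10, WM = 3, stride = 2), c(3, 5, 7, 9))
  expect_equal(maxPool1d(rep(2, 9)), rep(2, 4))
  brutePool <- function(v, WM, q) {
    n <- (length(v) - WM) %/% q + 1
    vapply(seq_len(n), function(i) max(v[((i - 1) * q + 1):((i - 1) * q + WM)]),
           numeric(1))
  }
  withr::with_seed(3, {
    for (i in 1:25) {
      L <- sample(3:40, 1)
      WM <- sample(seq_len(min(L, 5)), 1)
      q <- sample(1:3, 1)
      v <- rnorm(L)
      expect_equal(maxPool1d(v, WM, q), brutePool(v, WM, q))
      expect_length(maxPool1d(v, WM, q), (L - WM) %/% q + 1)
    }
  })
  expect_error(maxPool1d(1:2, WM = 3), "shorter")
})

test_that("the network architecture follows the half-window first-kernel
           rule", {
  cfg <- cnnBuild(4970, 6)
  expect_identical(cfg$F1, 2485L)
  expect_identical(cfg$F2, 10L)
  expect_identical(cfg$nFilters, 70L)
  cfg200 <- cnnBuild(200, 6)
  expect_identical(cfg200$F1, 100L)
  # flattened dimension: L1 = 101, pooled = 50, conv2 -> 41, x 70 filters
  expect_identical(cfg200$d, 41L * 70L)
  expect_error(cnnBuild(20, 6), "too small")
})

test_that("an untrained zero-initialised network outputs (0.5, 0.5) on a
           zero segment", {
  cfg <- cnnBuild(40, 2, epochs = 0L, initSD = 0, biasConst = 0)
  segs <- list(matrix(0, 40, 2), matrix(rnorm(80), 40, 2))
  net <- fitCNN(segs, labels = c(0L, 1L), config = cfg, seed = 1)
  pr <- cnnProbabilities(net, list(matrix(0, 40, 2)))
  expect_equal(unname(pr[1, ]), c(0.5, 0.5))
})

test_that("the convolutional network trains above chance on separable
           segments and is seed-reproducible", {
  ds <- tinyDataset(n0 = 6, n1 = 6, T = 120, delta = 2, seed = 44)
  std <- applyStandardizer(ds, fitStandardizer(ds))
  segs <- sampleSegments(std, W = 50, mPerSubject = 8, seed = 3)
  net <- fitCNN(segs, seed = 5)
  truth <- vapply(segs, function(s) s@group, integer(1))
  expect_gt(mean(predictClass(net, segs) == truth), 0.7)
  net2 <- fitCNN(segs, seed = 5)
  expect_identical(net@params, net2@params)
})

test_that("segment shape mismatches are rejected", {
  segs <- list(matrix(0, 30, 2), matrix(0, 40, 2))
  expect_error(fitCNN(segs, labels = c(0L, 1L)), "window length")
  cfg <- cnnBuild(40, 2)
  expect_error(fitCNN(list(matrix(0, 40, 3), matrix(1, 40, 3)),
                      labels = c(0L, 1L), config = cfg), "shape")
})
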