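test_that("LDA predictions equal direct evaluation of the decision
           inequality", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(c(16, 24, 40), 1)
      p <- sample(2:5, 1)
      fs <- randomFeatureSet(n, p, sep = runif(1, 0.5, 3), seed = 31 + i)
      model <- fitLDA(fs, ridge = 0)
      Xnew <- matrix(rnorm(8 * p), 8, p,
                     dimnames = list(NULL, colnames(fs@features)))
      # oracle: the printed rule from independently recomputed estimates
      X <- fs@features; y <- fs@labels
      mu0 <- colMeans(X[y == 0, , drop = FALSE])
      mu1 <- colMeans(X[y == 1, , drop = FALSE])
      S <- (crossprod(sweep(X[y == 0, , drop = FALSE], 2, mu0)) +
            crossprod(sweep(X[y == 1, , drop = FALSE], 2, mu1))) / (n - 2)
      d <- solve(S, mu1 - mu0)
      lhs <- as.numeric(Xnew %*% d)
      rhs <- 0.5 * sum((mu1 + mu0) * d) - log(mean(y) / (1 - mean(y)))
      expect_identical(predictClass(model, Xnew), as.integer(lhs > rhs))
    }
  })
})

test_that("LDA agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  withr::with_seed(5, {
    fs <- randomFeatureSet(n = 40, p = 3, sep = 1.5, seed = 5)
    model <- fitLDA(fs)
    Xnew <- matrix(rnorm(60), 20, 3,
                   dimnames = list(NULL, colnames(fs@features)))
    ref <- MASS::lda(fs@features, grouping = fs@labels)
    refPred <- as.integer(as.character(predict(ref, Xnew)$class))
    expect_identical(predictClass(model, Xnew), refPred)
  })
})

test_that("the symmetric LDA problem reduces to the perpendicular
           bisector and boundary ties go to class 0", {
  mu <- c(1, 0.5)
  X <- rbind(matrix(rep(-mu, 4), 4, 2, byrow = TRUE) + 0,
             matrix(rep(mu, 4), 4, 2, byrow = TRUE))
  # add symmetric scatter so the covariance is well-defined
  scatter <- rbind(c(.3, .1), c(-.3, -.1), c(.1, -.3), c(-.1, .3))
  X <- X + rbind(scatter, scatter)
  colnames(X) <- c("f1", "f2")
  fs <- new("LabeledFeatureSet", features = X,
            labels = rep(0:1, each = 4), subjectIDs = paste0("s", 1:8))
  model <- fitLDA(fs)
  # equal priors, mu0 = -mu1: boundary through the origin, rule = sign(x'w)
  expect_equal(decisionScore(model, matrix(c(0, 0), 1, 2,
    dimnames = list(NULL, c("f1", "f2")))), 0, tolerance = 1e-10)
  mid <- matrix((model@mu0 + model@mu1) / 2, 1, 2,
                dimnames = list(NULL, c("f1", "f2")))
  expect_identical(predictClass(model, mid), 0L)  # tie -> class 0
  expect_identical(predictClass(model, matrix(mu, 1, 2,
    dimnames = list(NULL, c("f1", "f2")))), 1L)
})

test_that("decision-rule and Fisher-projection classifications coincide", {
  withr::with_seed(17, {
    for (i in 1:10) {
      fs <- randomFeatureSet(n = 30, p = 4, sep = 1, seed = 170 + i)
      model <- fitLDA(fs)
      Xnew <- matrix(rnorm(40), 10, 4,
                     dimnames = list(NULL, colnames(fs@features)))
      z <- ldaProjection(model, Xnew)
      cut <- model@threshold  # prior-adjusted cut-point on the projection
      expect_identical(predictClass(model, Xnew), as.integer(z > cut))
    }
  })
})

test_that("two-point linear SVM recovers the analytic solution", {
  fs <- new("LabeledFeatureSet",
            features = matrix(c(-1, 1), 2, 1, dimnames = list(NULL, "x")),
            labels = c(0L, 1L), subjectIDs = c("a", "b"))
  model <- fitSVM(fs, kernel = "linear", cost = 1e3)
  expect_equal(unname(model@beta), 1, tolerance = 1e-3)
  expect_equal(model@beta0, 0, tolerance = 1e-3)
  expect_equal(model@margin, 1, tolerance = 1e-3)
  expect_identical(predictClass(model, matrix(2, 1, 1,
    dimnames = list(NULL, "x"))), 1L)
})

test_that("the radial-kernel gamma default is 1 / (p * Var(X))", {
  fs <- randomFeatureSet(n = 20, p = 5, sep = 1, seed = 3)
  model <- fitSVM(fs, kernel = "radial")
  v <- mean(fs@features^2) - mean(fs@features)^2
  expect_equal(model@gamma, 1 / (5 * v))
})

test_that("KKT conditions and the margin identity hold on random fits", {
  withr::with_seed(21, {
    for (i in 1:10) {
      fs <- randomFeatureSet(n = sample(c(20, 30), 1), p = 3,
                             sep = runif(1, 0, 2), seed = 210 + i)
      for (kern in c("linear", "radial")) {
        model <- fitSVM(fs, kernel = kern)
        kkt <- svmKKT(model, fs)
        expect_lt(kkt$maxViolation, 1e-2)
        if (kern == "linear") {
          expect_equal(kkt$marginIdentityError, 0, tolerance = 1e-10)
          # decision function recomputed from the primal form
          D <- as.numeric(fs@features %*% model@beta) + model@beta0
          expect_equal(D, decisionScore(model, fs@features),
                       tolerance = 1e-6)
        }
      }
    }
  })
})

test_that("random forest defaults and vote tally match the configuration", {
  fs <- randomFeatureSet(n = 30, p = 24, sep = 2, seed = 8)
  model <- fitRF(fs, mTrees = 25L, seed = 4)
  expect_identical(model@r, 5L)  # round(sqrt(24))
  votes <- rfTreeVotes(model, fs@features)
  expect_identical(ncol(votes), 25L)
  tally <- as.integer(rowMeans(votes) > 0.5)
  expect_identical(predictClass(model, fs@features), tally)
})

test_that("a single tree separates perfectly separable data and fits are
           seed-reproducible", {
  X <- matrix(c(rnorm(10, 0, .1), rnorm(10, 10, .1)), 20, 1,
              dimnames = list(NULL, "x"))
  fs <- new("LabeledFeatureSet", features = X,
            labels = rep(0:1, each = 10), subjectIDs = paste0("s", 1:20))
  tree <- fitRF(fs, mTrees = 1L, r = 1L, seed = 2)
  expect_identical(predictClass(tree, X), fs@labels)
  fs2 <- randomFeatureSet(n = 30, p = 4, sep = 0.5, seed = 6)
  m1 <- fitRF(fs2, mTrees = 50L, seed = 11)
  m2 <- fitRF(fs2, mTrees = 50L, seed = 11)
  expect_identical(predictClass(m1, fs2@features),
                   predictClass(m2, fs2@features))
})

test_that("single-class inputs are rejected by every family", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  fs <- new("LabeledFeatureSet", features = X, labels = rep(1L, 10),
            subjectIDs = paste0("s", 1:10))
  expect_error(fitLDA(fs), "both classes")
  expect_error(fitSVM(fs), "both classes")
  expect_error(fitRF(fs), "both classes")
  expect_error(fitFF(fs), "both classes")
})
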