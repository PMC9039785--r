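# small in-code fixtures shared across the suite

# compact synthetic dataset; defaults sized for fast tests
tinyDataset <- function(n0 = 5, n1 = 5, T = 120, delta = 1, seed = 1,
                        hands = "right", ...) {
  generateDataset(syntheticConfig(nGroup0 = n0, nGroup1 = n1, T = T,
                                  effectDelta = delta, seed = seed,
                                  hands = hands, ...))
}

# hand-built profile from an explicit matrix
madeProfile <- function(id, group, mat, rateHz = 10, height = 1.7,
                        handedness = "right") {
  new("MovementProfile", subjectID = id, group = as.integer(group),
      channels = mat, rateHz = rateHz, height = height,
      handedness = handedness)
}

madeDataset <- function(...) {
  new("MovementDataset", profiles = list(...), metadata = list())
}

# random labeled feature set with a class separation of size sep
randomFeatureSet <- function(n = 24, p = 4, sep = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] + sep * y
    colnames(X) <- paste0("f", seq_len(p))
    new("LabeledFeatureSet", features = X, labels = as.integer(y),
        subjectIDs = sprintf("s%02d", seq_len(n)))
  })
}
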