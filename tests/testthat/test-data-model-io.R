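test_that("pooled standardizer matches hand-computed values", {
  # two subjects, one channel, values {0,0} and {2,2}: pooled values
  # {0,0,2,2} -> mean 1, population SD 1
  ds <- madeDataset(
    madeProfile("a", 0, cbind(ch = c(0, 0))),
    madeProfile("b", 1, cbind(ch = c(2, 2))))
  par <- fitStandardizer(ds)
  expect_equal(unname(par@mean), 1)
  expect_equal(unname(par@sd), 1)
})

test_that("standardization is idempotent and invertible in distribution", {
  ds <- tinyDataset(n0 = 3, n1 = 3, T = 60, seed = 5)
  std <- applyStandardizer(ds, fitStandardizer(ds))
  par2 <- fitStandardizer(std)
  expect_equal(unname(par2@mean), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(par2@sd), rep(1, 6), tolerance = 1e-12)
  # identity parameters leave data unchanged
  idpar <- new("StandardizationParams",
               mean = setNames(rep(0, 6), channelNames(ds)),
               sd = setNames(rep(1, 6), channelNames(ds)),
               scope = "channel")
  same <- applyStandardizer(ds, idpar)
  expect_equal(channelMatrix(same[[1]]), channelMatrix(ds[[1]]))
})

test_that("standardizing an affine transform equals the original z-scores", {
  ds <- tinyDataset(n0 = 2, n1 = 2, T = 40, seed = 9)
  a <- 2.5; b <- -3
  shifted <- new("MovementDataset", profiles = lapply(profiles(ds),
    function(p) initialize(p, channels = a * p@channels + b)),
    metadata = list())
  z1 <- applyStandardizer(ds, fitStandardizer(ds))
  z2 <- applyStandardizer(shifted, fitStandardizer(shifted))
  expect_equal(channelMatrix(z2[[1]]), channelMatrix(z1[[1]]),
               tolerance = 1e-12)
})

test_that("constant channels are rejected with the channel named", {
  ds <- madeDataset(
    madeProfile("a", 0, cbind(flat = c(1, 1), ok = c(0, 1))),
    madeProfile("b", 1, cbind(flat = c(1, 1), ok = c(2, 3))))
  expect_error(fitStandardizer(ds), "flat")
})

test_that("global-scope standardization pools across channels", {
  ds <- tinyDataset(n0 = 2, n1 = 2, T = 30, seed = 3)
  par <- fitStandardizer(ds, scope = "global")
  expect_equal(length(unique(par@mean)), 1L)
  expect_equal(length(unique(par@sd)), 1L)
  stacked <- do.call(rbind, lapply(profiles(ds), channelMatrix))
  expect_equal(unname(par@mean[1]), mean(stacked))
})

test_that("channel mismatch between dataset and parameters errors", {
  ds <- tinyDataset(n0 = 2, n1 = 2, T = 30, seed = 3)
  par <- fitStandardizer(ds)
  other <- madeDataset(madeProfile("x", 0, cbind(zz = rnorm(5))))
  expect_error(applyStandardizer(other, par), "mismatch")
})

test_that("write/read round-trips a dataset bit-exactly", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(syntheticConfig(nGroup0 = 2, nGroup1 = 2, T = 40,
                                        hands = "both", seed = 8), "study2")
  manifest <- writeDataset(ds, dir)
  back <- readDataset(manifest)
  expect_identical(subjectIDs(back), subjectIDs(ds))
  expect_identical(groupLabels(back), groupLabels(ds))
  for (i in seq_along(profiles(ds))) {
    expect_identical(channelMatrix(back[[i]]), channelMatrix(ds[[i]]))
    expect_identical(back[[i]]@handedness, ds[[i]]@handedness)
    expect_equal(back[[i]]@height, ds[[i]]@height)
  }
})

test_that("readDataset rejects corrupt manifests", {
  dir <- withr::local_tempdir()
  ds <- tinyDataset(n0 = 2, n1 = 1, T = 20, seed = 2)
  manifest <- writeDataset(ds, dir)
  expect_error(readDataset(file.path(dir, "nope.csv")), "not found")
  man <- read.csv(manifest, colClasses = c(subject_id = "character"))
  man$subject_id[2] <- man$subject_id[1]
  bad <- file.path(dir, "dup.csv")
  write.csv(man, bad, row.names = FALSE)
  expect_error(readDataset(bad), "duplicate")
  file.remove(file.path(dir, man$file[3]))
  expect_error(readDataset(manifest), "missing")
})

test_that("dataset validity catches structural violations", {
  p1 <- madeProfile("a", 0, cbind(x = 1:3 / 1))
  p2 <- madeProfile("a", 1, cbind(x = 4:6 / 1))
  expect_error(madeDataset(p1, p2), "unique")
  p3 <- madeProfile("b", 1, cbind(zz = 4:6 / 1))
  expect_error(madeDataset(p1, p3), "channel names")
  expect_error(madeProfile("c", 0, cbind(x = c(1, NA))), "missing")
})

test_that("hand selection strips suffixes and honours handedness", {
  ds <- generateDataset(syntheticConfig(nGroup0 = 2, nGroup1 = 2, T = 30,
                                        hands = "both", seed = 12), "study2")
  right <- selectHandChannels(ds, "right")
  expect_identical(channelNames(right),
                   c("global_x", "global_y", "global_z",
                     "local_x", "local_y", "local_z"))
  byh <- selectHandChannels(ds, "by_handedness")
  i <- which(vapply(profiles(ds), function(p) p@handedness,
                    character(1)) == "left")[1]
  if (!is.na(i)) {
    expect_equal(channelMatrix(byh[[i]])[, "local_y"],
                 unname(channelMatrix(ds[[i]])[, "local_y_left"]))
  }
  onlyRight <- tinyDataset(n0 = 1, n1 = 1, T = 20, hands = "right")
  expect_error(selectHandChannels(onlyRight, "left"), "lacks")
})
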